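# Hand-rolled PDB record writer so parser tests do not depend on the
# package's own writer.
pdb_line <- function(record = "ATOM", serial, name, resname, chain, resno,
                     x, y, z, occ = 1, b = 0, element = "", alt = "",
                     icode = "") {
  name_field <- if (nchar(name) < 4) sprintf(" %-3s", name)
  else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_field, alt, resname, chain, resno, icode,
          x, y, z, occ, b, element)
}

write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
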