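# Hand-crafted fixed-width PDB records for parser contract tests.

pdb_line <- function(serial, name, alt, resn, chain, resseq, x, y, z,
                     occ = 1, b = 0, el = "C", rec = "ATOM  ") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, alt, resn, chain, resseq, " ", x, y, z, occ, b,
          el)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# one ALA residue with 5 atoms at arbitrary positions
ala_lines <- function(resseq = 1, offset = c(0, 0, 0)) {
  o <- offset
  c(pdb_line(1, "N", "", "ALA", "A", resseq, 0 + o[1], 0 + o[2], 0 + o[3],
             el = "N"),
    pdb_line(2, "CA", "", "ALA", "A", resseq, 1.46 + o[1], 0 + o[2],
             0 + o[3]),
    pdb_line(3, "C", "", "ALA", "A", resseq, 2.0 + o[1], 1.4 + o[2],
             0 + o[3]),
    pdb_line(4, "O", "", "ALA", "A", resseq, 1.5 + o[1], 2.5 + o[2],
             0 + o[3], el = "O"),
    pdb_line(5, "CB", "", "ALA", "A", resseq, 2.0 + o[1], -1.2 + o[2],
             1.0 + o[3]))
}
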