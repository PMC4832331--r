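#!/usr/bin/env Rscript
# Downloads the public reference inputs used by the two
# reference-reproduction tests in tests/testthat/test-acceptance.R:
#
#   - UniProt P0A9H3 (E. coli LdcI / CadA) and P52095 (E. coli LdcC),
#     combined into inst/extdata/reference/ldcI_ldcC_ecoli.fasta
#   - RCSB biological-assembly mmCIF files for the decamer models
#     3N75 (LdcI, inactive-pH crystal), 5FKX (LdcI at active pH),
#     5FKZ (LdcC) and 5FL2 (LdcI-LARA)
#
# Requires network access. Run from the repository root, then reinstall
# the package so the files are picked up by system.file().

dest <- file.path("inst", "extdata", "reference")
dir.create(dest, recursive = TRUE, showWarnings = FALSE)

fetch <- function(url, to) {
  message("fetching ", url)
  utils::download.file(url, to, quiet = TRUE, mode = "wb")
}

tmp_i <- tempfile(); tmp_c <- tempfile()
fetch("https://rest.uniprot.org/uniprotkb/P0A9H3.fasta", tmp_i)
fetch("https://rest.uniprot.org/uniprotkb/P52095.fasta", tmp_c)
parse_fa <- function(f) {
  l <- readLines(f)
  paste(l[!startsWith(l, ">")], collapse = "")
}
writeLines(c(">LdcI P0A9H3", parse_fa(tmp_i),
             ">LdcC P52095", parse_fa(tmp_c)),
           file.path(dest, "ldcI_ldcC_ecoli.fasta"))

for (id in c("3N75", "5FKX", "5FKZ", "5FL2")) {
  fetch(sprintf("https://files.rcsb.org/download/%s-assembly1.cif", id),
        file.path(dest, sprintf("%s-assembly1.cif", id)))
}
message("done; reinstall the package to expose the files via system.file()")
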