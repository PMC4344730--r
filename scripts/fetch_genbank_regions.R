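#!/usr/bin/env Rscript

# Optional helper (requires network access): fetches the GenBank regions
# listed by helhunt::cited_regions() via NCBI efetch and writes them as
# FASTA, with reverse-cited spans (start > end) reverse-complemented by
# extract_region(). The offline test suite never calls this script.
#
# Usage: Rscript scripts/fetch_genbank_regions.R [out.fasta]

suppressMessages(library(helhunt))

out <- commandArgs(trailingOnly = TRUE)
out <- if (length(out)) out[1] else "cited_regions.fasta"

regions <- cited_regions()
base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
               "efetch.fcgi?db=nuccore&rettype=fasta&retmode=text&id=")

pieces <- lapply(seq_len(nrow(regions)), function(k) {
  acc <- regions$accession[k]
  tmp <- tempfile(fileext = ".fasta")
  utils::download.file(paste0(base, acc), tmp, quiet = TRUE)
  full <- read_fasta(tmp)
  full$id <- acc
  extract_region(full, acc, regions$start[k], regions$end[k])
})

write_fasta(dplyr::bind_rows(pieces), out)
cat(sprintf("wrote %d regions to %s\n", nrow(regions), out))
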