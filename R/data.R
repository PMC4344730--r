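# Bundled example data

#' Example comparative-divergence matrices for six lepidopteran species
#'
#' Published percent-identity matrices for Hel-2 Helitron copies
#' (`te`) and the RpS5 ribosomal-protein housekeeping gene (`host`)
#' across Ostrinia nubilalis, Plutella xylostella, Trichoplusia ni,
#' Helicoverpa armigera, Choristoneura fumiferana and Bombyx mori
#' (GenBank accessions JX683313.1, JN383812.1, AY837869.1, KF624964.1,
#' FE273699.1, AY769319.1). Two species pairs show higher TE than host
#' identity: feeding these matrices to [compare_matrices()] flags
#' exactly those two pairs.
#'
#' @return list with `te` and `host` `identity_matrix` objects.
#' @export
#' @examples
#' m <- hel2_example_matrices()
#' compare_matrices(m$te, m$host)
hel2_example_matrices <- function() {
  list(
    te = read_identity_tsv(system.file("extdata",
                                       "hel2_identity_6taxa.tsv",
                                       package = "helhunt")),
    host = read_identity_tsv(system.file("extdata",
                                         "rps5_identity_6taxa.tsv",
                                         package = "helhunt"))
  )
}

#' GenBank regions used by the documented element alignments
#'
#' Accession coordinates of the Hel-2/MITE01 regions referenced by the
#' package documentation, recorded verbatim (including one internally
#' inconsistent span length, noted but not corrected). Reverse
#' citations (start > end) denote the reverse complement, as understood
#' by [extract_region()]. Fetching the sequences requires network
#' access; see `scripts/fetch_genbank_regions.R` in the source
#' repository.
#'
#' @return tibble of accession, start, end, species, note.
#' @export
cited_regions <- function() {
  as_tibble(read.delim(system.file("extdata", "cited_regions.tsv",
                                   package = "helhunt"),
                       check.names = FALSE))
}
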