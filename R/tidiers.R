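# broom-style tidiers for the package's result objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an HTT screen
#'
#' @param x an `htt_screen`.
#' @param ... unused.
#' @return one row per species pair with delta, flag and p-value.
#' @export
tidy.htt_screen <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of an HTT screen
#'
#' @param x an `htt_screen`.
#' @param ... unused.
#' @return a tibble with pair counts, the top pair and its statistics.
#' @export
glance.htt_screen <- function(x, ...) {
  top <- x[1, ]
  tibble(n_pairs = nrow(x), n_flagged = sum(x$flagged),
         top_pair = paste(top$species_a, top$species_b, sep = "~"),
         top_delta = top$delta, top_p_value = top$p_value,
         n_perm = attr(x, "n_perm"),
         identity_mode = attr(x, "identity_mode"))
}

#' Tidy an element annotation into a feature table
#'
#' @param x a `hel_annotation`.
#' @param ... unused.
#' @return a tibble of features (type, coordinates, detail).
#' @export
tidy.hel_annotation <- function(x, ...) {
  f <- annotation_features(x)
  f$tier <- x$tier
  f
}

#' One-row summary of an element annotation
#'
#' @param x a `hel_annotation`.
#' @param ... unused.
#' @return a tibble with tier and feature counts.
#' @export
glance.hel_annotation <- function(x, ...) {
  tibble(id = x$id, length = x$length, tier = x$tier,
         n_termini = nrow(x$termini), has_hairpin = nrow(x$hairpin) > 0,
         hairpin_dg = if (nrow(x$hairpin)) x$hairpin$dg else NA_real_,
         n_ir = nrow(x$irs), n_microsat = nrow(x$microsatellites))
}

#' Tidy an identity matrix into a long pair table
#'
#' @param x an `identity_matrix`.
#' @param ... unused.
#' @return a tibble with `species_a`, `species_b`, `identity`.
#' @export
tidy.identity_matrix <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(species_a = labs[idx[, 1]], species_b = labs[idx[, 2]],
         identity = x[idx])
}
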