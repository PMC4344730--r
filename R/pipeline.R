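# End-to-end orchestration: scan -> annotate -> align -> htt -> phylo,
# with a YAML-serialisable config and a provenance manifest.

#' Pipeline configuration
#'
#' All module thresholds with their documented defaults. Round-trips
#' through YAML unchanged.
#'
#' @param query path to the query element FASTA.
#' @param subjects path to the subject (genome/contig) FASTA.
#' @param host_marker optional path to a per-species host-marker FASTA
#'   (enables the HTT stage; ids must match subject ids).
#' @param out_dir output directory.
#' @param min_identity,max_evalue,min_terminal homology filters.
#' @param end_slack full-length end slack (bases).
#' @param gamma gamma shape parameter for the T3P model.
#' @param bootstrap bootstrap pseudoreplicates.
#' @param support_floor consensus support floor (percent).
#' @param n_perm HTT permutation count.
#' @param identity_mode identity mode for both TE and host matrices
#'   (recorded in output metadata).
#' @param seed integer seed.
#' @return a `run_config` list.
#' @export
run_config <- function(query, subjects, host_marker = NULL,
                       out_dir = "helhunt_out", min_identity = 65,
                       max_evalue = 1e-5, min_terminal = 50, end_slack = 5,
                       gamma = 2.249, bootstrap = 1000, support_floor = 50,
                       n_perm = 999, identity_mode = "all_columns",
                       seed = 1) {
  structure(list(query = query, subjects = subjects,
                 host_marker = host_marker, out_dir = out_dir,
                 min_identity = min_identity, max_evalue = max_evalue,
                 min_terminal = min_terminal, end_slack = end_slack,
                 gamma = gamma, bootstrap = bootstrap,
                 support_floor = support_floor, n_perm = n_perm,
                 identity_mode = identity_mode, seed = seed),
            class = "run_config")
}

#' Read / write a pipeline config as YAML
#' @param path YAML path.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param config a `run_config`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_log <- function(manifest, stage, ...) {
  info <- list(...)
  msg <- paste(sprintf("%s=%s", names(info), unlist(info)), collapse = " ")
  message(sprintf("[%s] %s", stage, msg))
  manifest$stages[[stage]] <- info
  manifest
}

#' Run the full detection + HTT pipeline
#'
#' Stages: scan (homology search + filters), annotate (structural
#' workup of hit regions), align (MSA + identity matrix of per-species
#' representative elements), htt (comparative divergence screen;
#' requires a host marker set), phylo (bootstrap consensus tree of the
#' elements). Each stage writes its output under `out_dir`; a manifest
#' with the effective config, per-stage counts and file checksums is
#' written as JSON. Any stage failure aborts with a stage-named error.
#'
#' @param config a [run_config()].
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c(config$query, config$subjects, config$host_marker)) {
    if (!is.null(f) && !file.exists(f)) {
      abort(sprintf("[input] missing input file: %s", f))
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "helhunt",
                   version = as.character(utils::packageVersion("helhunt")),
                   config = unclass(config), stages = list())
  # --- scan ---
  query <- read_fasta(config$query)
  subjects <- read_fasta(config$subjects)
  if (!nrow(subjects)) abort("[scan] subject FASTA has no sequences")
  if (!nrow(query)) abort("[scan] query FASTA has no sequences")
  hits <- scan_sequences(subjects, query[1, ],
                         min_identity = config$min_identity,
                         max_evalue = config$max_evalue,
                         min_terminal = config$min_terminal,
                         end_slack = config$end_slack)
  hits_path <- file.path(config$out_dir, "hits.tsv")
  write.table(hits, hits_path, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- stage_log(manifest, "scan", subjects = nrow(subjects),
                        hits_retained = nrow(hits))
  # --- annotate ---
  elements <- hit_sequences(hits, subjects)
  annos <- if (nrow(elements)) annotate_elements(elements) else
    annotate_elements(seq_tbl(character()))
  if (nrow(annos)) {
    feats <- bind_rows(lapply(annos$annotation, annotation_features))
  } else {
    feats <- tibble(seq_id = character(), start = integer(),
                    end = integer())
  }
  gff_path <- file.path(config$out_dir, "annotations.gff3")
  write_annotations(feats, gff_path, format = "gff3")
  el_path <- file.path(config$out_dir, "elements.fasta")
  write_fasta(elements, el_path)
  tier_counts <- table(factor(annos$tier, levels = c("full", "partial",
                                                     "structural_only",
                                                     "rejected")))
  manifest <- stage_log(manifest, "annotate", elements = nrow(annos),
                        full = tier_counts[["full"]],
                        partial = tier_counts[["partial"]])
  # --- align: one representative element per subject (best-scoring hit) ---
  rep_hits <- hits %>%
    group_by(.data$subject_id) %>%
    filter(row_number() == 1) %>%
    ungroup()
  rep_seqs <- hit_sequences(rep_hits, subjects)
  rep_seqs$id <- rep_hits$subject_id
  te_matrix <- NULL
  if (nrow(rep_seqs) >= 2) {
    aln <- progressive_msa(rep_seqs)
    te_matrix <- identity_matrix(aln, mode = config$identity_mode)
    write_identity_tsv(te_matrix,
                       file.path(config$out_dir, "te_identity.tsv"))
  }
  manifest <- stage_log(manifest, "align", species = nrow(rep_seqs))
  # --- htt ---
  screen <- NULL
  if (!is.null(config$host_marker) && !is.null(te_matrix)) {
    marker <- read_fasta(config$host_marker)
    marker <- marker[marker$id %in% rownames(te_matrix), ]
    if (nrow(marker) >= 2) {
      host_matrix <- identity_matrix(progressive_msa(marker),
                                     mode = config$identity_mode)
      common <- intersect(rownames(te_matrix), rownames(host_matrix))
      screen <- htt_screen(te_matrix[common, common],
                           host_matrix[common, common],
                           n_perm = config$n_perm, seed = config$seed,
                           identity_mode = config$identity_mode)
      write.table(as.data.frame(screen),
                  file.path(config$out_dir, "htt.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      manifest <- stage_log(manifest, "htt", pairs = nrow(screen),
                            flagged = sum(screen$flagged))
    }
  }
  # --- phylo ---
  if (nrow(rep_seqs) >= 4) {
    aln <- progressive_msa(rep_seqs)
    model <- phylo_model(gamma_shape = config$gamma)
    tree <- bootstrap_consensus(aln, model, n_reps = config$bootstrap,
                                support_floor = config$support_floor,
                                seed = config$seed)
    ape::write.tree(tree, file.path(config$out_dir, "consensus_tree.nwk"))
    manifest <- stage_log(manifest, "phylo", taxa = nrow(rep_seqs),
                          bootstrap = config$bootstrap)
  }
  # --- manifest ---
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$checksums <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write / read a labelled identity matrix as TSV
#' @param m an `identity_matrix`.
#' @param path TSV path.
#' @return `path` (write) or an `identity_matrix` (read).
#' @export
write_identity_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_identity_tsv
#' @export
read_identity_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  structure(m, class = c("identity_matrix", "matrix", "array"))
}
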