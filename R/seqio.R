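#' @useDynLib helhunt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter arrange select bind_rows desc group_by
#'   ungroup summarise left_join row_number across all_of n
#' @importFrom rlang .data abort warn
#' @importFrom stats setNames runif rbinom
#' @importFrom utils head tail write.table read.delim modifyList
#' @keywords internal
"_PACKAGE"

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

COMPLEMENT_FROM <- "ACGTRYSWKMBDHVN"
COMPLEMENT_TO   <- "TGCAYRSWMKVHDBN"

new_seq_tbl <- function(id, description, residues) {
  tibble(
    id = as.character(id),
    description = as.character(description),
    residues = toupper(as.character(residues)),
    length = nchar(residues)
  )
}

#' Construct a sequence tibble from named DNA strings
#'
#' The package carries DNA sequences in a plain tibble with columns
#' `id`, `description`, `residues` (uppercase IUPAC DNA) and `length`.
#'
#' @param x named character vector of DNA strings, or an unnamed vector
#'   (ids are generated as `seq1`, `seq2`, ...).
#' @param description optional description column (recycled).
#' @return a sequence tibble.
#' @export
#' @examples
#' seq_tbl(c(el1 = "ACGTACGT"))
seq_tbl <- function(x, description = "") {
  ids <- names(x)
  x <- toupper(as.character(x))
  if (is.null(ids)) ids <- paste0("seq", seq_along(x))
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_DNA, collapse = "")), x)
  if (any(bad)) {
    abort(sprintf("illegal residue in sequence '%s'", ids[which(bad)[1]]))
  }
  new_seq_tbl(ids, description, x)
}

seq_string <- function(x, id = NULL) {
  # accept a 1-row (or id-selected) sequence tibble, or a plain string
  if (is.character(x) && length(x) == 1 && !is.null(x)) return(toupper(x))
  stopifnot(is.data.frame(x))
  if (!is.null(id)) x <- x[x$id == id, , drop = FALSE]
  if (nrow(x) != 1) abort("expected exactly one sequence")
  x$residues[[1]]
}

#' Reverse complement of DNA strings
#'
#' IUPAC ambiguity codes are complemented to their mirror codes; `N`
#' stays `N`.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr(COMPLEMENT_FROM, COMPLEMENT_TO, toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Read a FASTA file into a sequence tibble
#'
#' One row per record, input order preserved. Residues are validated
#' against the IUPAC DNA alphabet (case-insensitive, stored uppercase);
#' duplicate record ids are rejected.
#'
#' @param path path to a FASTA file.
#' @return a sequence tibble (`id`, `description`, `residues`, `length`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) == 0]
  if (length(lines) == 0) {
    return(new_seq_tbl(character(), character(), character())[0, ])
  }
  hdr <- grepl("^>", lines)
  if (!hdr[1]) {
    abort(sprintf("malformed FASTA: line 1 of %s is not a header", path))
  }
  bad_hdr <- which(hdr & !grepl("^>\\S", lines))
  if (length(bad_hdr)) {
    abort(sprintf("malformed header at line %d of %s", bad_hdr[1], path))
  }
  pattern <- sprintf("[^%s%s]", paste(IUPAC_DNA, collapse = ""),
                     tolower(paste(IUPAC_DNA, collapse = "")))
  bad_res <- which(!hdr & grepl(pattern, lines))
  if (length(bad_res)) {
    abort(sprintf("illegal residue at line %d of %s", bad_res[1], path))
  }
  rec <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sequence id '%s' in %s",
                  ids[duplicated(ids)][1], path))
  }
  body <- vapply(seq_along(ids), function(k) {
    paste(lines[!hdr & rec == k], collapse = "")
  }, character(1))
  new_seq_tbl(ids, desc, body)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs sequence tibble.
#' @param path output path.
#' @param width residues per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(seqs))) {
    hdr <- if (nzchar(seqs$description[k])) {
      paste(seqs$id[k], seqs$description[k])
    } else {
      seqs$id[k]
    }
    writeLines(paste0(">", hdr), con)
    s <- seqs$residues[k]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a GenBank flat file (sequence and identity only)
#'
#' Parses LOCUS, DEFINITION and ORIGIN records; feature tables are
#' ignored. Multi-record files are supported.
#'
#' @param path path to a GenBank flat file.
#' @return a sequence tibble.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec_start <- grep("^LOCUS", lines)
  if (length(rec_start) == 0) abort(sprintf("no LOCUS record in %s", path))
  rec_end <- c(rec_start[-1] - 1, length(lines))
  recs <- lapply(seq_along(rec_start), function(k) {
    block <- lines[rec_start[k]:rec_end[k]]
    id <- strsplit(trimws(sub("^LOCUS", "", block[1])), "\\s+")[[1]][1]
    # VERSION line carries the accession.version when present
    ver <- grep("^VERSION", block, value = TRUE)
    if (length(ver)) {
      v <- strsplit(trimws(sub("^VERSION", "", ver[1])), "\\s+")[[1]][1]
      if (nzchar(v)) id <- v
    }
    defl <- grep("^DEFINITION", block)
    desc <- ""
    if (length(defl)) {
      dend <- defl[1]
      while (dend < length(block) && grepl("^\\s", block[dend + 1])) {
        dend <- dend + 1
      }
      desc <- paste(trimws(sub("^DEFINITION", "", block[defl[1]:dend])),
                    collapse = " ")
    }
    ori <- grep("^ORIGIN", block)
    if (length(ori) == 0) abort(sprintf("record %s has no ORIGIN", id))
    endl <- grep("^//", block)
    endl <- if (length(endl)) endl[1] - 1 else length(block)
    body <- block[(ori[1] + 1):endl]
    residues <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    list(id = id, desc = desc, residues = residues)
  })
  new_seq_tbl(vapply(recs, `[[`, character(1), "id"),
              vapply(recs, `[[`, character(1), "desc"),
              vapply(recs, `[[`, character(1), "residues"))
}

#' Extract a region from a stored sequence
#'
#' Coordinates are 1-based inclusive. A `start` greater than `end`
#' follows the GenBank citation convention (e.g. "positions 1429 to
#' 1179") and returns the reverse complement of the forward span
#' `[end, start]`. The returned length is always `abs(start - end) + 1`.
#'
#' @param seqs sequence tibble.
#' @param seq_id id of the sequence to slice (may be omitted when `seqs`
#'   has a single row).
#' @param start,end 1-based inclusive positions.
#' @param strand `"+"` or `"-"`; `"-"` reverse-complements the span (in
#'   addition to the start > end convention).
#' @return a 1-row sequence tibble; the new id records the slice.
#' @export
extract_region <- function(seqs, seq_id = NULL, start, end, strand = "+") {
  s <- seq_string(seqs, seq_id)
  if (is.null(seq_id)) seq_id <- seqs$id[[1]]
  n <- nchar(s)
  lo <- min(start, end); hi <- max(start, end)
  if (lo < 1 || hi > n) {
    abort(sprintf("region [%d,%d] out of bounds for %s (length %d)",
                  start, end, seq_id, n))
  }
  sub <- substr(s, lo, hi)
  rc <- (start > end) != (strand == "-")
  if (rc) sub <- revcomp(sub)
  new_seq_tbl(sprintf("%s:%d-%d(%s)", seq_id, start, end,
                      if (rc) "-" else "+"),
              sprintf("region of %s", seq_id), sub)
}

# --- annotation serialization ----------------------------------------------

std_anno <- function(annos) {
  need <- c("seq_id", "start", "end")
  if (!all(need %in% names(annos))) {
    abort("annotations need columns seq_id, start, end")
  }
  annos$strand <- if ("strand" %in% names(annos)) annos$strand else "+"
  annos$type <- if ("type" %in% names(annos)) annos$type else "helitron"
  annos$name <- if ("name" %in% names(annos)) {
    annos$name
  } else {
    sprintf("%s_%d", annos$type, seq_len(nrow(annos)))
  }
  annos$score <- if ("score" %in% names(annos)) annos$score else 0
  if (nrow(annos) && any(annos$start > annos$end)) {
    abort("annotation with start > end")
  }
  if (nrow(annos) && any(annos$start < 1)) abort("annotation start < 1")
  annos
}

#' Write annotations as BED or GFF3
#'
#' Input coordinates are 1-based inclusive; BED output is 0-based
#' half-open, GFF3 output 1-based inclusive. [read_annotations()]
#' inverts the conversion so round-trips preserve coordinates exactly.
#'
#' @param annos tibble with `seq_id`, `start`, `end` and optionally
#'   `strand`, `type`, `name`, `score`.
#' @param path output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annos, path, format = c("bed", "gff3")) {
  if (!is.character(format) || !all(format %in% c("bed", "gff3"))) {
    abort(sprintf("unknown annotation format '%s'", format[1]))
  }
  format <- match.arg(format)
  annos <- std_anno(annos)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "bed") {
    writeLines("#seq_id\tstart\tend\tname\tscore\tstrand", con)
    if (nrow(annos)) {
      writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                         annos$seq_id, as.integer(annos$start) - 1L,
                         as.integer(annos$end), annos$name,
                         format(annos$score, trim = TRUE), annos$strand), con)
    }
  } else {
    writeLines("##gff-version 3", con)
    if (nrow(annos)) {
      writeLines(sprintf("%s\thelhunt\t%s\t%d\t%d\t%s\t%s\t.\tID=%s",
                         annos$seq_id, annos$type, as.integer(annos$start),
                         as.integer(annos$end),
                         format(annos$score, trim = TRUE), annos$strand,
                         annos$name), con)
    }
  }
  invisible(path)
}

#' Read annotations written by [write_annotations()]
#'
#' @param path input path.
#' @param format `"bed"` or `"gff3"`.
#' @return tibble with 1-based inclusive `start`/`end`.
#' @export
read_annotations <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character(),
                  type = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "bed") {
    tibble(
      seq_id = vapply(f, `[[`, character(1), 1),
      start = as.integer(vapply(f, `[[`, character(1), 2)) + 1L,
      end = as.integer(vapply(f, `[[`, character(1), 3)),
      name = vapply(f, `[[`, character(1), 4),
      score = as.numeric(vapply(f, `[[`, character(1), 5)),
      strand = vapply(f, `[[`, character(1), 6),
      type = "helitron"
    )
  } else {
    tibble(
      seq_id = vapply(f, `[[`, character(1), 1),
      start = as.integer(vapply(f, `[[`, character(1), 4)),
      end = as.integer(vapply(f, `[[`, character(1), 5)),
      name = sub("^ID=", "", vapply(f, `[[`, character(1), 9)),
      score = suppressWarnings(as.numeric(vapply(f, `[[`, character(1), 6))),
      strand = vapply(f, `[[`, character(1), 7),
      type = vapply(f, `[[`, character(1), 3)
    )
  }
}

# --- Clustal-format alignment I/O ------------------------------------------

#' Write an alignment in Clustal format
#' @param aln alignment object (see [pairwise_global()]).
#' @param path output path.
#' @param width columns per block.
#' @return `path`, invisibly.
#' @export
write_clustal <- function(aln, path, width = 60) {
  ids <- aln$id
  seqs <- aln$aligned
  w <- max(nchar(ids)) + 3
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CLUSTAL W multiple sequence alignment\n", con)
  len <- nchar(seqs[1])
  for (st in seq(1, len, by = width)) {
    for (k in seq_along(ids)) {
      writeLines(sprintf("%-*s%s", w, ids[k],
                         substr(seqs[k], st, min(st + width - 1, len))), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a Clustal-format alignment
#' @param path input path.
#' @return an alignment tibble (`id`, `aligned`).
#' @export
read_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[-1]  # header line
  body <- lines[nzchar(trimws(lines)) & !grepl("^[[:space:]*:.]+$", lines)]
  parts <- strsplit(trimws(body), "\\s+")
  parts <- parts[vapply(parts, length, integer(1)) >= 2]
  ids <- vapply(parts, `[[`, character(1), 1)
  segs <- vapply(parts, `[[`, character(1), 2)
  uids <- unique(ids)
  seqs <- vapply(uids, function(i) paste(segs[ids == i], collapse = ""),
                 character(1))
  new_alignment(uids, unname(seqs))
}
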