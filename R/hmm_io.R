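# I/O: HMMER3 tblout import, delimited score matrices, label tables.

#' Read HMMER3 per-target tabular output (tblout)
#'
#' Parses the whitespace-delimited per-target table written by
#' `hmmsearch --tblout` / `hmmscan --tblout`: '#' comment lines are skipped,
#' fields 1/3 are target/query names, field 5 is the full-sequence E-value
#' and field 6 the full-sequence bit score; the free-text description tail is
#' ignored. With `hmmsearch` the profile is the query and the sequence the
#' target; with `hmmscan` the orientation is reversed — set `orientation`
#' accordingly.
#'
#' @param path path to a tblout file.
#' @param orientation `"hmmsearch"` (default: target = sequence,
#'   query = profile) or `"hmmscan"` (target = profile, query = sequence).
#' @return data frame with columns `sequence_id`, `profile_id`, `score`,
#'   `evalue`; zero rows for a file with only comments.
#' @export
read_tblout <- function(path, orientation = c("hmmsearch", "hmmscan")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  records <- lapply(which(keep), function(ln) {
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) < 6) {
      stop("malformed tblout line ", ln, ": fewer than 6 fields", call. = FALSE)
    }
    evalue <- suppressWarnings(as.numeric(fields[5]))
    score <- suppressWarnings(as.numeric(fields[6]))
    if (is.na(evalue) || is.na(score)) {
      stop(
        "malformed tblout line ", ln, ": non-numeric E-value/score fields",
        call. = FALSE
      )
    }
    if (evalue < 0) {
      stop("malformed tblout line ", ln, ": negative E-value", call. = FALSE)
    }
    data.frame(
      target = fields[1], query = fields[3], score = score, evalue = evalue
    )
  })
  if (length(records) == 0) {
    return(data.frame(
      sequence_id = character(0), profile_id = character(0),
      score = numeric(0), evalue = numeric(0)
    ))
  }
  rec <- do.call(rbind, records)
  if (orientation == "hmmsearch") {
    data.frame(
      sequence_id = rec$target, profile_id = rec$query,
      score = rec$score, evalue = rec$evalue
    )
  } else {
    data.frame(
      sequence_id = rec$query, profile_id = rec$target,
      score = rec$score, evalue = rec$evalue
    )
  }
}

#' Assemble a score matrix from hit records
#'
#' Builds the sequences x functions matrix from parsed hits. Profiles are
#' mapped to function labels through `function_map`; duplicate hits for the
#' same (sequence, function) cell keep the maximum score (best hit); cells
#' with no hit are imputed 0 (the floor after clamping), and sequences
#' missing more than `drop_missing_over` of the functions are dropped.
#' Assembly is order-independent: shuffling `records` yields the same
#' matrix.
#'
#' @param records data frame from [read_tblout()] (columns `sequence_id`,
#'   `profile_id`, `score`).
#' @param function_map named character vector mapping profile ids to function
#'   labels; must cover >= 3 distinct labels. Defaults to the identity map
#'   over the profiles present.
#' @param sequence_universe optional character vector fixing the row set (and
#'   order); sequences with no hits at all then appear as all-imputed rows.
#' @param drop_missing_over drop sequences missing hits for more than this
#'   fraction of functions (default 0.5).
#' @param clamp_negative passed to [score_matrix()].
#' @return a [score_matrix()] with attributes `imputed` (number of imputed
#'   cells) and `dropped` (ids of dropped sequences).
#' @export
build_score_matrix <- function(records, function_map = NULL,
                               sequence_universe = NULL,
                               drop_missing_over = 0.5,
                               clamp_negative = TRUE) {
  if (is.null(function_map)) {
    profiles <- sort(unique(records$profile_id))
    function_map <- stats::setNames(profiles, profiles)
  }
  labels <- unique(unname(function_map))
  if (length(labels) < 3) {
    stop(
      "function_map covers only ", length(labels),
      " label(s); the axiom min|A| = 3 requires at least 3",
      call. = FALSE
    )
  }
  records <- records[records$profile_id %in% names(function_map), , drop = FALSE]
  seqs <- sequence_universe %||% sort(unique(records$sequence_id))
  mat <- matrix(NA_real_,
    nrow = length(seqs), ncol = length(labels),
    dimnames = list(seqs, labels)
  )
  for (r in seq_len(nrow(records))) {
    sid <- records$sequence_id[r]
    if (!sid %in% seqs) next
    lab <- unname(function_map[[records$profile_id[r]]])
    cur <- mat[sid, lab]
    mat[sid, lab] <- if (is.na(cur)) records$score[r] else max(cur, records$score[r])
  }
  missing_frac <- rowMeans(is.na(mat))
  dropped <- rownames(mat)[missing_frac > drop_missing_over]
  if (length(dropped) > 0) {
    message(
      length(dropped), " sequence(s) dropped: missing hits for more than ",
      drop_missing_over * 100, "% of functions"
    )
    mat <- mat[missing_frac <= drop_missing_over, , drop = FALSE]
  }
  imputed <- sum(is.na(mat))
  if (imputed > 0) {
    message(imputed, " missing (sequence, function) cell(s) imputed as 0")
    mat[is.na(mat)] <- 0
  }
  out <- score_matrix(mat, clamp_negative = clamp_negative)
  attr(out, "imputed") <- imputed
  attr(out, "dropped") <- dropped
  out
}

#' Read a delimited score matrix
#'
#' Expected layout: header row of function labels, first column of sequence
#' ids, tab- (or `sep`-) delimited numeric scores.
#'
#' @param path input file.
#' @param sep field separator (default tab).
#' @param clamp_negative passed to [score_matrix()].
#' @return a [score_matrix()].
#' @export
read_score_matrix <- function(path, sep = "\t", clamp_negative = TRUE) {
  df <- utils::read.table(path,
    header = TRUE, sep = sep, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- ids
  score_matrix(mat, clamp_negative = clamp_negative)
}

#' Write a score matrix as TSV
#'
#' @param scores a [score_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(scores, path) {
  v <- as_score_values(scores)
  df <- data.frame(sequence_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sequence label table
#'
#' TSV with columns `sequence_id` and `function_label`, and optionally `ssi`
#' (a pre-computed sequence suitability index). When the `ssi` column is
#' present, rows with `ssi <= 1.00` are filtered out — only sequences
#' passing that threshold are suitable for training. The index itself is
#' never computed here; it is consumed as a ready-made filter column.
#'
#' @param path input file.
#' @param sep field separator (default tab).
#' @return named character vector: labels named by sequence id.
#' @export
read_labels <- function(path, sep = "\t") {
  df <- utils::read.table(path,
    header = TRUE, sep = sep, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  need <- c("sequence_id", "function_label")
  if (!all(need %in% names(df))) {
    stop(
      "label file must have columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if ("ssi" %in% names(df)) {
    drop <- df$ssi <= 1.00
    if (any(drop)) {
      message(sum(drop), " sequence(s) filtered out by SSI <= 1.00")
    }
    df <- df[!drop, , drop = FALSE]
  }
  stats::setNames(as.character(df$function_label), df$sequence_id)
}

#' Sequence ids from a FASTA file
#'
#' Bookkeeping helper for defining the sequence universe; sequences
#' themselves are never used.
#'
#' @param path FASTA file.
#' @return character vector of ids.
#' @export
read_fasta_ids <- function(path) {
  if (requireNamespace("seqinr", quietly = TRUE)) {
    names(seqinr::read.fasta(path, seqonly = FALSE, as.string = TRUE))
  } else {
    lines <- readLines(path, warn = FALSE)
    heads <- lines[startsWith(lines, ">")]
    sub("\\s.*$", "", substring(heads, 2))
  }
}
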