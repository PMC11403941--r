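#' Read a FASTA file into a sequence table
#'
#' Sequences are uppercase-normalised and restricted to the \{A,C,G,T,N\}
#' alphabet. In strict mode any other character is an error; in lenient mode
#' offending characters are mapped to N with a warning.
#'
#' @param path Path to a FASTA file.
#' @param strict Logical; reject alphabet violations and duplicate ids
#'   (default `TRUE`). When `FALSE`, violations are repaired with a warning.
#' @return A `data.frame` with columns `id` and `seq`, one row per record,
#'   input order preserved.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty id")
  if (anyDuplicated(ids)) {
    if (strict) stop("duplicate FASTA ids: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", "))
    warning("duplicate FASTA ids retained (lenient mode)")
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (strict) {
      stop("non-ACGTN characters in record(s): ",
           paste(ids[bad], collapse = ", "))
    }
    warning("non-ACGTN characters mapped to N in ",
            sum(bad), " record(s)")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  if (any(nchar(seqs) < 1L)) stop("zero-length sequence in FASTA")
  data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' @param records A `data.frame` with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line width for the sequence body.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a TSS table (BED6-like TSV)
#'
#' Expected columns: contig, pos (0-based TSS coordinate), gene_id, score
#' (ignored), strand. An optional header line is detected by a non-numeric
#' `pos` field.
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` with columns `contig`, `pos`, `gene_id`, `strand`.
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty TSS table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 5L)) {
    stop("TSS table line(s) with fewer than 5 tab-separated fields: line ",
         which(n_col < 5L)[1L])
  }
  # header detection: pos field not parseable as a number
  first_pos <- suppressWarnings(as.numeric(fields[[1L]][2L]))
  if (is.na(first_pos)) {
    fields <- fields[-1L]
    if (length(fields) == 0L) stop("TSS table has a header but no records")
  }
  contig <- vapply(fields, `[[`, "", 1L)
  pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  gene_id <- vapply(fields, `[[`, "", 3L)
  strand <- vapply(fields, `[[`, "", 5L)
  if (anyNA(pos)) stop("non-numeric pos at line ", which(is.na(pos))[1L])
  if (any(pos < 0)) stop("negative pos at line ", which(pos < 0)[1L])
  if (any(pos != floor(pos))) stop("non-integer pos")
  bad_strand <- !(strand %in% c("+", "-"))
  if (any(bad_strand)) {
    stop("strand not in {+,-} at line ", which(bad_strand)[1L])
  }
  key <- paste(contig, gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (contig, gene_id) pair: ",
         sub("\r", "/", key[duplicated(key)][1L]))
  }
  data.frame(contig = contig, pos = as.integer(pos), gene_id = gene_id,
             strand = strand, stringsAsFactors = FALSE)
}

#' Read a TRANSFAC-like count matrix
#'
#' The dialect is: an `ID` (or `NA`) line carrying the matrix name, an
#' optional `P0 A C G T` column-header line, one row per position of the form
#' `pos A C G T`, and a `//` terminator. Counts must be non-negative.
#'
#' @param path Path to a matrix file.
#' @return An object of class `pwm_counts`: a list with elements `name` and
#'   `counts` (L x 4 integer-valued matrix, columns A,C,G,T).
#' @seealso [build_pwm()], [as_pwm()]
#' @export
read_matrix_transfac <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  name <- NULL
  rows <- list()
  for (ln in lines) {
    if (ln == "//") break
    tag <- sub("\\s.*$", "", ln)
    if (tag %in% c("ID", "NA")) {
      name <- trimws(sub("^\\S+\\s*", "", ln))
      next
    }
    if (tag == "P0" || tag == "PO") next
    parts <- strsplit(ln, "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    vals <- vals[!is.na(vals)]
    if (length(vals) != 4L) {
      stop("matrix row without exactly 4 numeric count fields: '", ln, "'")
    }
    if (any(vals < 0)) stop("negative count in matrix row: '", ln, "'")
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) stop("no count rows found in ", path)
  counts <- do.call(rbind, rows)
  colnames(counts) <- DNA_BASES
  pwm_counts(counts, name %||% "matrix")
}

#' Write a TRANSFAC-like count matrix
#'
#' @param x A `pwm_counts` or `pwm` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_transfac <- function(x, path) {
  counts <- x$counts
  lines <- c(
    paste("NA", x$name),
    paste("P0", paste(DNA_BASES, collapse = " ")),
    vapply(seq_len(nrow(counts)), function(i) {
      paste(sprintf("%02d", i), paste(format(counts[i, ], trim = TRUE,
                                             scientific = FALSE),
                                      collapse = " "))
    }, ""),
    "//"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Construct a pwm_counts object
#'
#' @param counts L x 4 non-negative matrix, columns ordered A,C,G,T.
#' @param name Matrix name.
#' @return A `pwm_counts` object.
#' @export
pwm_counts <- function(counts, name = "matrix") {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop("counts must have 4 columns (A,C,G,T)")
  if (nrow(counts) < 1L) stop("counts must have at least one row")
  if (any(counts < 0)) stop("negative counts")
  colnames(counts) <- DNA_BASES
  structure(list(name = name, counts = counts), class = "pwm_counts")
}

#' Write a tabular result deterministically
#'
#' Tab-separated, one header line, deterministic column order (as given),
#' doubles at 6 significant digits. Two runs on identical input produce
#' byte-identical files.
#'
#' @param records A `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(records, path) {
  records <- as.data.frame(records)
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(signif(out[[j]], 6L), format = "g", digits = 6L)
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open path for writing: ", path)
  })
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0L) {
    body <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}
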