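#' Extract strand-aware promoter windows around TSSs
#'
#' Coordinates are 0-based half-open throughout. For a TSS at genomic
#' position `t`, the window covers `upstream` bases before the start site and
#' `downstream` bases from the start site onwards in transcript orientation;
#' the TSS base itself is the first downstream base. On the plus strand the
#' genomic interval is `[t - upstream, t + downstream)` and the sequence is
#' taken as-is; on the minus strand it is `[t - downstream + 1, t + upstream
#' + 1)` and the sequence is reverse-complemented, so all returned sequences
#' read 5' to 3' of the gene. The defaults (2900 bp upstream, 100 bp
#' downstream) give 3000 bp promoters; a -1000/+100 analysis window is a
#' common narrower variant.
#'
#' @param genome A `data.frame` with columns `id` and `seq` (contigs), as
#'   returned by [read_fasta()].
#' @param tss A `data.frame` with columns `contig`, `pos`, `gene_id`,
#'   `strand`, as returned by [read_tss_table()].
#' @param upstream,downstream Window extents in bp (`upstream + downstream
#'   >= 1`).
#' @param clip If `TRUE`, windows exceeding contig bounds are clipped to the
#'   contig (with a message); if `FALSE` (default) they raise an error naming
#'   the gene.
#' @return A `data.frame` with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open genomic interval), `strand`, `seq`, `set_label`
#'   (initially `"unlabeled"`).
#' @export
extract_promoters <- function(genome, tss, upstream = 2900L,
                              downstream = 100L, clip = FALSE) {
  if (upstream + downstream < 1L) stop("upstream + downstream must be >= 1")
  contig_len <- setNames(nchar(genome$seq), genome$id)
  missing_contig <- setdiff(tss$contig, genome$id)
  if (length(missing_contig)) {
    stop("contig(s) named in TSS table absent from genome: ",
         paste(missing_contig, collapse = ", "))
  }
  n <- nrow(tss)
  start <- integer(n); end <- integer(n); seqs <- character(n)
  for (i in seq_len(n)) {
    t <- tss$pos[i]
    len <- contig_len[[tss$contig[i]]]
    if (tss$strand[i] == "+") {
      s <- t - upstream; e <- t + downstream
    } else {
      s <- t - downstream + 1L; e <- t + upstream + 1L
    }
    if (s < 0L || e > len) {
      if (!clip) {
        stop("promoter window for gene '", tss$gene_id[i],
             "' exceeds contig bounds [0,", len, "): [", s, ",", e, ")")
      }
      message("clipping promoter window for gene '", tss$gene_id[i], "'")
      s <- max(s, 0L); e <- min(e, len)
    }
    sq <- substring(genome$seq[genome$id == tss$contig[i]][1L], s + 1L, e)
    if (tss$strand[i] == "-") sq <- revcomp(sq)
    start[i] <- s; end[i] <- e; seqs[i] <- sq
  }
  data.frame(gene_id = tss$gene_id, contig = tss$contig, start = start,
             end = end, strand = tss$strand, seq = seqs,
             set_label = "unlabeled", stringsAsFactors = FALSE)
}

#' Assign regulated/control set labels to promoters
#'
#' Genes are assigned by the magnitude of their strongest treatment response
#' (maximum `|log2fc|` across treatments): at least `fold_strong`-fold with
#' an FDR pass gives `regulated_gt4`; between `fold_mod`- and
#' `fold_strong`-fold with an FDR pass gives `regulated_2to4`. Control genes
#' must look flat in every treatment: `|fold change| < control_max_fold` and
#' raw p `> control_min_p` throughout. Everything else (including genes
#' absent from the expression table, which are warned about) stays
#' `unlabeled`.
#'
#' @param promoters Promoter table from [extract_promoters()].
#' @param expr Expression table from [compute_differential()] (per gene and
#'   treatment: `log2fc`, `p_raw`, `p_fdr`).
#' @param fold_strong,fold_mod Fold-change boundaries (defaults 4 and 2).
#' @param fdr FDR threshold for the regulated classes (default 0.05).
#' @param control_max_fold,control_min_p Non-regulation rule for controls
#'   (defaults 1.2 and 0.5).
#' @return The promoter table with `set_label` filled in; labels partition
#'   the labeled genes.
#' @export
assign_set_labels <- function(promoters, expr, fold_strong = 4, fold_mod = 2,
                              fdr = 0.05, control_max_fold = 1.2,
                              control_min_p = 0.5) {
  lab <- rep("unlabeled", nrow(promoters))
  missing <- setdiff(promoters$gene_id, expr$gene)
  if (length(missing)) {
    warning("gene(s) absent from expression table left unlabeled: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ..." else "")
  }
  for (i in seq_len(nrow(promoters))) {
    rows <- expr[expr$gene == promoters$gene_id[i], , drop = FALSE]
    if (nrow(rows) == 0L) next
    afc <- abs(rows$log2fc)
    sig <- rows$p_fdr < fdr
    if (any(afc >= log2(fold_strong) & sig)) {
      lab[i] <- "regulated_gt4"
    } else if (any(afc >= log2(fold_mod) & sig)) {
      lab[i] <- "regulated_2to4"
    } else if (all(afc < log2(control_max_fold)) &&
               all(rows$p_raw > control_min_p)) {
      lab[i] <- "control"
    }
  }
  promoters$set_label <- lab
  promoters
}

#' Format promoter FASTA headers
#'
#' Header layout: `gene|label|contig:start-end(strand)`.
#'
#' @param promoters Promoter table.
#' @return Character vector of headers.
#' @export
promoter_headers <- function(promoters) {
  sprintf("%s|%s|%s:%d-%d(%s)", promoters$gene_id, promoters$set_label,
          promoters$contig, promoters$start, promoters$end, promoters$strand)
}
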