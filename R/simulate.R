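#' Simulate aligned binding-site sequences
#'
#' Two modes. PWM mode (`pwm` given): each base is drawn independently from
#' the matrix column frequencies. Consensus mode (`consensus` given): each
#' sequence starts as the consensus and every base is substituted
#' independently with probability `mutation_rate` by one of the three other
#' bases. The default `n = 44` mirrors a typical published binding-site
#' collection size.
#'
#' @param n Number of sequences (default 44).
#' @param pwm A `pwm` object (PWM mode), or `NULL`.
#' @param consensus A consensus string (consensus mode), or `NULL`.
#' @param mutation_rate Per-base substitution probability in `[0, 1]`
#'   (consensus mode; default 0).
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of `n` equal-length sequences.
#' @export
simulate_binding_sites <- function(n = 44L, pwm = NULL, consensus = NULL,
                                   mutation_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]")
  }
  if (is.null(pwm) == is.null(consensus)) {
    stop("give exactly one of pwm or consensus")
  }
  if (!is.null(pwm)) {
    L <- nrow(pwm$freq)
    sites <- vapply(seq_len(n), function(i) {
      paste(vapply(seq_len(L), function(j) {
        sample(DNA_BASES, 1L, prob = pwm$freq[j, ])
      }, ""), collapse = "")
    }, "")
    return(sites)
  }
  base <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  L <- length(base)
  vapply(seq_len(n), function(i) {
    b <- base
    mut <- stats::runif(L) < mutation_rate
    if (any(mut)) {
      b[mut] <- vapply(b[mut], function(x) sample(setdiff(DNA_BASES, x), 1L),
                       "")
    }
    paste(b, collapse = "")
  }, "")
}

#' Simulate promoter sequences with planted motif occurrences
#'
#' Background bases are drawn i.i.d. from `base_probs`. Each promoter
#' receives `Poisson(lambda * length / 1000)` planted sites, sampled either
#' as exact consensus copies or from the PWM column frequencies, placed
#' uniformly on a random strand without overlapping previously planted
#' sites (rejection sampling with bounded retries). Planting positions,
#' strands and site sequences are recorded as ground truth. The default
#' 1100 bp length mirrors a -1000/+100 promoter analysis window.
#'
#' @param n_promoters Number of promoters (default 200).
#' @param length Promoter length in bp (default 1100).
#' @param lambda Planted sites per 1000 bp (>= 0).
#' @param pwm A `pwm` object for the planted motif (needed when
#'   `lambda > 0`).
#' @param mode `"consensus"` (exact rank-1 consensus copies) or `"pwm"`
#'   (sites drawn from the matrix).
#' @param base_probs Background base probabilities for A,C,G,T (sum 1).
#' @param set_label Label stored on the generated promoters.
#' @param max_tries Placement retries per site before giving up.
#' @param seed Optional integer seed.
#' @return List with `promoters` (`id`, `seq`, `set_label`) and `truth`
#'   (`promoter_id`, `offset`, `strand`, `matrix`, `site_seq`).
#' @export
simulate_promoters <- function(n_promoters = 200L, length = 1100L,
                               lambda = 0, pwm = NULL,
                               mode = c("consensus", "pwm"),
                               base_probs = rep(0.25, 4L),
                               set_label = "unlabeled",
                               max_tries = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mode <- match.arg(mode)
  if (lambda < 0) stop("lambda must be >= 0")
  if (abs(sum(base_probs) - 1) > 1e-9) stop("base_probs must sum to 1")
  if (lambda > 0 && is.null(pwm)) stop("pwm required when lambda > 0")
  L <- if (!is.null(pwm)) nrow(pwm$freq) else 0L
  cons <- if (!is.null(pwm)) consensus(pwm, 1L) else NULL
  ids <- sprintf("prom%04d", seq_len(n_promoters))
  seqs <- character(n_promoters)
  truth <- list()
  for (i in seq_len(n_promoters)) {
    s <- sample(DNA_BASES, length, replace = TRUE, prob = base_probs)
    n_sites <- if (lambda > 0) stats::rpois(1L, lambda * length / 1000) else 0L
    occupied <- integer(0)
    placed <- 0L
    tries <- 0L
    while (placed < n_sites) {
      tries <- tries + 1L
      if (tries > max_tries * max(n_sites, 1L)) {
        stop("could not place ", n_sites, " non-overlapping sites of length ",
             L, " in a ", length, " bp promoter (lambda too large?)")
      }
      off <- sample.int(length - L + 1L, 1L) - 1L  # 0-based
      span <- (off + 1L):(off + L)
      if (any(span %in% occupied)) next
      site <- if (mode == "consensus") cons else
        simulate_binding_sites(1L, pwm = pwm)
      strand <- sample(c("+", "-"), 1L)
      s[span] <- strsplit(if (strand == "+") site else revcomp(site), "",
                          fixed = TRUE)[[1L]]
      occupied <- c(occupied, span)
      placed <- placed + 1L
      truth[[length(truth) + 1L]] <- data.frame(
        promoter_id = ids[i], offset = off, strand = strand,
        matrix = pwm$name, site_seq = site, stringsAsFactors = FALSE)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(promoter_id = character(), offset = integer(),
               strand = character(), matrix = character(),
               site_seq = character(), stringsAsFactors = FALSE)
  list(promoters = data.frame(id = ids, seq = seqs, set_label = set_label,
                              stringsAsFactors = FALSE),
       truth = truth)
}

default_shared_design <- function() {
  c("T1+T2" = 8L, "T1+T3" = 6L, "T1+T4" = 7L, "T2+T3" = 10L, "T2+T4" = 9L,
    "T3+T4" = 10L, "T1+T2+T3" = 1L, "T1+T2+T4" = 1L, "T2+T3+T4" = 1L)
}

#' Simulate a multi-treatment expression table with planted DEG structure
#'
#' Null genes get replicate log2 ratios `Normal(0, sigma)` in every
#' treatment. Planted genes get `Normal(+/-effect, sigma)` in their
#' designated treatments, with the effect magnitude drawn uniformly from
#' `effect_range`. Treatment memberships honour the requested unique and
#' shared counts exactly; directions are assigned so that `n_up` of the
#' planted genes are up-regulated (in all their treatments) and the rest
#' down. The defaults emulate a four-arm dose-regimen design: unique DEG
#' counts 102/52/20/79 per treatment, 53 genes shared between treatments
#' (306 planted DEGs in total, 181 up and 125 down), six biological
#' replicates, and replicate noise sigma = 0.25 log2 units.
#'
#' @param n_genes Total genes (default 2000).
#' @param treatments Treatment names (at most the four defaults are used by
#'   the shared design; default `T1..T4`).
#' @param unique_counts Named (or positionally matched) integer vector of
#'   per-treatment unique DEG counts.
#' @param shared Named integer vector; names are treatment combinations
#'   joined with `+` (e.g. `"T1+T2"`), values the number of genes planted in
#'   exactly those treatments. Default [default_shared_design()].
#' @param n_up Number of planted genes that are up-regulated (default 181);
#'   the remaining planted genes are down-regulated.
#' @param effect_range Range of `|log2fc|` for planted effects
#'   (default `c(1.5, 3.5)`).
#' @param sigma Replicate noise standard deviation in log2 units
#'   (default 0.25).
#' @param n_reps Replicates per (gene, treatment) (default 6).
#' @param seed Optional integer seed.
#' @return List with `ratios` (long `data.frame`: `gene`, `treatment`,
#'   `replicate`, `log_ratio`) and `truth` (`gene`, `treatments`
#'   (`+`-joined), `direction`, `effect`).
#' @export
simulate_expression <- function(n_genes = 2000L,
                                treatments = c("T1", "T2", "T3", "T4"),
                                unique_counts = c(T1 = 102L, T2 = 52L,
                                                  T3 = 20L, T4 = 79L),
                                shared = default_shared_design(),
                                n_up = 181L,
                                effect_range = c(1.5, 3.5),
                                sigma = 0.25, n_reps = 6L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(unique_counts))) names(unique_counts) <- treatments
  memberships <- c(as.list(names(unique_counts)),
                   lapply(names(shared), function(s)
                     strsplit(s, "+", fixed = TRUE)[[1L]]))
  counts <- c(unname(unique_counts), unname(shared))
  bad <- !unlist(lapply(memberships, function(m) all(m %in% treatments)))
  if (any(bad)) stop("shared design names treatments outside 'treatments'")
  n_planted <- sum(counts)
  if (n_planted > n_genes) {
    stop("requested DEG counts (", n_planted, ") exceed n_genes (", n_genes,
         ")")
  }
  if (n_up > n_planted) stop("n_up exceeds the number of planted genes")
  genes <- sprintf("g%05d", seq_len(n_genes))
  planted <- sample(genes, n_planted)
  assign <- rep(seq_along(memberships), counts)
  direction <- rep("down", n_planted)
  direction[sample.int(n_planted, n_up)] <- "up"
  effect <- stats::runif(n_planted, effect_range[1L], effect_range[2L])
  truth <- data.frame(
    gene = planted,
    treatments = vapply(assign, function(i)
      paste(memberships[[i]], collapse = "+"), ""),
    direction = direction,
    effect = effect * ifelse(direction == "up", 1, -1),
    stringsAsFactors = FALSE
  )
  mean_of <- matrix(0, nrow = n_genes, ncol = length(treatments),
                    dimnames = list(genes, treatments))
  for (j in seq_len(n_planted)) {
    mean_of[planted[j], memberships[[assign[j]]]] <- truth$effect[j]
  }
  grid <- expand.grid(replicate = seq_len(n_reps), treatment = treatments,
                      gene = genes, stringsAsFactors = FALSE)
  mu <- mean_of[cbind(grid$gene, grid$treatment)]
  grid$log_ratio <- stats::rnorm(nrow(grid), mean = mu, sd = sigma)
  list(ratios = grid[, c("gene", "treatment", "replicate", "log_ratio")],
       truth = truth)
}
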