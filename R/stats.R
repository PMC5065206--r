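#' Friedman test and post-hoc pairwise comparisons
#'
#' The statistical protocol for comparing irregularity scores across the
#' three diagnostic classes: a blocked Friedman rank test at alpha = 0.05
#' followed by all-pairs comparisons adjusted with the Holm, Shaffer, and
#' Bergmann-Hommel procedures.
#'
#' @name stats_module
#' @keywords internal
NULL

#' Arrange per-class scores into Friedman blocks
#'
#' The evaluation images are unpaired across classes, while the Friedman
#' test requires blocks with one observation per class. Blocks are formed by
#' shuffling the rows of each class with a seeded permutation and pairing
#' the i-th image of each class, which requires equal class sizes.
#'
#' @param scores data frame with a `class` column and score columns.
#' @param metric name of the score column to block.
#' @param seed integer seed for the within-class shuffles.
#' @param classes class order (default: order of first appearance).
#' @return numeric `n x k` matrix, one column per class.
#' @export
make_blocks <- function(scores, metric, seed = 1L, classes = NULL) {
  if (!metric %in% names(scores)) stop("unknown metric column: ", metric)
  if (is.null(classes)) classes <- unique(as.character(scores$class))
  groups <- lapply(classes, function(cl) scores[[metric]][scores$class == cl])
  n <- lengths(groups)
  if (length(unique(n)) != 1L) stop("blocks undefined: unequal class sizes")
  if (anyNA(unlist(groups))) stop("blocks undefined: missing score values")
  set.seed(seed)
  blocks <- vapply(groups, function(g) g[sample.int(length(g))], numeric(n[1]))
  colnames(blocks) <- classes
  blocks
}

#' Friedman rank test
#'
#' Within each block (row) the k group scores are ranked ascending, average
#' ranks for ties, so rank 1 goes to the smallest (least irregular) score.
#' The tie-corrected chi-square statistic is
#' `12 * sum((R_j - n(k+1)/2)^2) / (n k (k+1) - T/(k-1))` where `R_j` are
#' rank column sums and `T` the usual tie term; the p-value comes from the
#' chi-square distribution with `k - 1` degrees of freedom. If every block
#' is completely tied the statistic is a 0/0 limit and is defined as 0
#' (p-value 1): identical groups carry no evidence against the null.
#'
#' @param blocks numeric `n x k` matrix (blocks by groups), `k >= 2`.
#' @return list with `statistic`, `p.value`, `mean_ranks`, `n`, `k`.
#' @export
friedman_rank_test <- function(blocks) {
  blocks <- as.matrix(blocks)
  n <- nrow(blocks); k <- ncol(blocks)
  if (k < 2L) stop("need at least 2 groups")
  if (anyNA(blocks)) stop("blocks undefined: missing values")
  r <- t(apply(blocks, 1L, rank))
  R <- colSums(r)
  ties <- sum(apply(blocks, 1L, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  }))
  denom <- n * k * (k + 1) - ties / (k - 1)
  # every block fully tied: numerator and tie-corrected denominator are both
  # exactly 0; the test carries no information, so the statistic is 0
  stat <- if (denom <= 0) 0 else 12 * sum((R - n * (k + 1) / 2)^2) / denom
  mean_ranks <- R / n
  names(mean_ranks) <- colnames(blocks)
  list(statistic = stat,
       p.value = pchisq(stat, df = k - 1, lower.tail = FALSE),
       mean_ranks = mean_ranks, n = n, k = k)
}

#' Raw pairwise p-values from Friedman mean ranks
#'
#' For groups i, j the statistic is
#' `z = (Rbar_i - Rbar_j) / sqrt(k (k+1) / (6 n))`, compared against the
#' standard normal (two-sided).
#'
#' @param mean_ranks named vector of mean ranks.
#' @param n number of blocks.
#' @return data frame with columns `a`, `b` (group names), `z`, `p`.
#' @export
pairwise_raw_pvalues <- function(mean_ranks, n) {
  k <- length(mean_ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  nm <- names(mean_ranks)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  pairs <- combn(k, 2)
  data.frame(
    a = nm[pairs[1, ]], b = nm[pairs[2, ]],
    z = (mean_ranks[pairs[1, ]] - mean_ranks[pairs[2, ]]) / se,
    p = 2 * pnorm(-abs(mean_ranks[pairs[1, ]] - mean_ranks[pairs[2, ]]) / se),
    row.names = NULL
  )
}

check_pvalues <- function(p) {
  if (!length(p) || any(p < 0 | p > 1) || anyNA(p))
    stop("p-values must lie in [0, 1]")
  p
}

#' Holm step-down adjustment
#'
#' Classic step-down Bonferroni: the i-th smallest p-value is multiplied by
#' `m - i + 1`, adjusted values are made monotone nondecreasing and capped
#' at 1 (delegates to [stats::p.adjust()]).
#'
#' @param p raw p-values.
#' @return adjusted p-values in input order.
#' @export
holm_adjust <- function(p) {
  p.adjust(check_pvalues(p), method = "holm")
}

# Possible numbers of simultaneously-true pairwise hypotheses among k groups:
# S(k) = union over block sizes j of {choose(j,2) + s : s in S(k - j)}.
shaffer_true_counts <- function(k) {
  if (k == 0L) return(0L)
  out <- integer(0)
  for (j in seq_len(k)) {
    out <- c(out, choose(j, 2) + shaffer_true_counts(k - j))
  }
  sort(unique(as.integer(out)))
}

#' Shaffer static step-down adjustment
#'
#' Step-down over the all-pairs family of `k` groups where the multiplier at
#' step i is the largest number of hypotheses that can still be
#' simultaneously true given i - 1 rejections (for k = 3 the sequence is
#' 3, 1, 1). Monotone-enforced and capped at 1.
#'
#' @param p raw p-values for all `k (k - 1) / 2` pairs.
#' @param k_groups number of groups.
#' @return adjusted p-values in input order.
#' @export
shaffer_adjust <- function(p, k_groups) {
  check_pvalues(p)
  m <- k_groups * (k_groups - 1) / 2
  if (length(p) != m)
    stop("expected ", m, " p-values for the all-pairs family of ", k_groups, " groups")
  s <- shaffer_true_counts(k_groups)
  mult <- vapply(seq_len(m), function(i) max(s[s <= m - i + 1]), numeric(1))
  o <- order(p)
  adj <- pmin(cummax(mult * p[o]), 1)
  adj[order(o)]
}

# All set partitions of 1..k (Bell number; k is small).
set_partitions <- function(k) {
  if (k == 1L) return(list(list(1L)))
  sub <- set_partitions(k - 1L)
  out <- list()
  for (p in sub) {
    for (i in seq_along(p)) {
      q <- p; q[[i]] <- c(q[[i]], k)
      out[[length(out) + 1L]] <- q
    }
    p[[length(p) + 1L]] <- k
    out[[length(out) + 1L]] <- p
  }
  out
}

#' Bergmann-Hommel dynamic adjustment
#'
#' For the all-pairs family, an index set of hypotheses is *exhaustive* if
#' exactly those hypotheses can be simultaneously true; these are generated
#' by the set partitions of the groups (hypotheses joining groups in the
#' same partition block). The adjusted p-value of hypothesis i is
#' `max over exhaustive sets E containing i of |E| * min(p[E])`, capped at
#' 1. Never exceeds the Shaffer adjustment; for k = 3 the two coincide.
#'
#' @param p raw p-values, ordered as `combn(k_groups, 2)` pairs.
#' @param k_groups number of groups (at most 5; the enumeration is
#'   exhaustive).
#' @return adjusted p-values in input order.
#' @export
bergmann_adjust <- function(p, k_groups) {
  check_pvalues(p)
  if (k_groups > 5L) stop("exhaustive enumeration refused for more than 5 groups")
  m <- k_groups * (k_groups - 1) / 2
  if (length(p) != m)
    stop("expected ", m, " p-values for the all-pairs family of ", k_groups, " groups")
  pairs <- combn(k_groups, 2)
  pair_id <- function(a, b) which(pairs[1, ] == min(a, b) & pairs[2, ] == max(a, b))
  exhaustive <- list()
  for (part in set_partitions(k_groups)) {
    ids <- integer(0)
    for (block in part) {
      if (length(block) >= 2L) {
        bp <- combn(block, 2)
        ids <- c(ids, vapply(seq_len(ncol(bp)),
                             function(j) pair_id(bp[1, j], bp[2, j]), integer(1)))
      }
    }
    if (length(ids)) exhaustive[[length(exhaustive) + 1L]] <- sort(ids)
  }
  exhaustive <- unique(exhaustive)
  adj <- vapply(seq_len(m), function(i) {
    vals <- vapply(exhaustive, function(E) {
      if (i %in% E) length(E) * min(p[E]) else NA_real_
    }, numeric(1))
    min(max(vals, na.rm = TRUE), 1)
  }, numeric(1))
  pmax(adj, p)
}

#' Per-metric Friedman report with post-hoc pairwise significance
#'
#' For each requested metric: Friedman test over seeded blocks, pairwise
#' raw p-values from the mean ranks, Holm / Shaffer / Bergmann-Hommel
#' adjustments, and the list of class pairs significant at `alpha` under
#' each procedure (post-hoc pairs are only declared when the omnibus test
#' itself rejects). `test = "kruskal"` replaces the blocked protocol with a
#' Kruskal-Wallis test and pairwise Wilcoxon rank-sum raw p-values for
#' unpaired data; this is an escape hatch, not the reference protocol.
#'
#' @param scores data frame with `class` and score columns (equal class
#'   sizes for the Friedman path).
#' @param metrics score column names (default: all numeric columns).
#' @param alpha significance level in (0, 1).
#' @param seed seed for the block pairing.
#' @param test `"friedman"` (default) or `"kruskal"`.
#' @return object of class `irr_significance`; its print method mirrors the
#'   p-value / significant-pairs summary table layout.
#' @export
significance_table <- function(scores, metrics = NULL, alpha = 0.05, seed = 1L,
                               test = c("friedman", "kruskal")) {
  test <- match.arg(test)
  if (!"class" %in% names(scores)) stop("scores must have a 'class' column")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (is.null(metrics)) {
    metrics <- names(scores)[vapply(scores, is.numeric, logical(1))]
    metrics <- setdiff(metrics, c("image_id", "block_id"))
  }
  classes <- unique(as.character(scores$class))
  k <- length(classes)
  per_metric <- lapply(metrics, function(m) {
    if (test == "friedman") {
      blocks <- make_blocks(scores, m, seed = seed, classes = classes)
      ft <- friedman_rank_test(blocks)
      pw <- pairwise_raw_pvalues(ft$mean_ranks, ft$n)
    } else {
      ft0 <- kruskal.test(scores[[m]], factor(scores$class, levels = classes))
      ft <- list(statistic = unname(ft0$statistic), p.value = ft0$p.value,
                 mean_ranks = NULL, n = nrow(scores), k = k)
      pairs <- combn(k, 2)
      pw <- data.frame(
        a = classes[pairs[1, ]], b = classes[pairs[2, ]], z = NA_real_,
        p = vapply(seq_len(ncol(pairs)), function(j) {
          suppressWarnings(stats::wilcox.test(
            scores[[m]][scores$class == classes[pairs[1, j]]],
            scores[[m]][scores$class == classes[pairs[2, j]]]
          )$p.value)
        }, numeric(1))
      )
    }
    pw$holm <- holm_adjust(pw$p)
    pw$shaffer <- shaffer_adjust(pw$p, k)
    pw$bergmann <- bergmann_adjust(pw$p, k)
    omnibus_rejects <- ft$p.value < alpha
    for (proc in c("holm", "shaffer", "bergmann")) {
      pw[[paste0("sig_", proc)]] <- omnibus_rejects & pw[[proc]] < alpha
    }
    list(metric = m, statistic = ft$statistic, p.value = ft$p.value,
         mean_ranks = ft$mean_ranks, pairwise = pw)
  })
  names(per_metric) <- metrics
  structure(list(test = test, alpha = alpha, classes = classes,
                 metrics = per_metric),
            class = "irr_significance")
}

#' @export
print.irr_significance <- function(x, ...) {
  cat(sprintf("%s test with post-hoc pairwise comparisons (alpha = %g)\n\n",
              if (x$test == "friedman") "Friedman" else "Kruskal-Wallis", x$alpha))
  cat(sprintf("%-22s %-12s %s\n", "Metric", "p-value", "Significant pairs (Holm)"))
  for (m in x$metrics) {
    sig <- m$pairwise[m$pairwise$sig_holm, , drop = FALSE]
    pairs <- if (nrow(sig)) paste(paste(sig$a, "vs", sig$b), collapse = ", ") else "Nil"
    cat(sprintf("%-22s %-12.3e %s\n", m$metric, m$p.value, pairs))
  }
  invisible(x)
}
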