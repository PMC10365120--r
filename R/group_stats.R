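#' Subjects-by-nodes matrix for one metric from a long profile table
#'
#' @param profiles data frame in the [profile_schema] layout (one tract /
#'   hemisphere at a time).
#' @param metric one of "fa", "md", "ad", "rd".
#' @return numeric matrix, one row per subject (rownames = subject ids),
#'   one column per node.
#' @export
node_matrix <- function(profiles, metric) {
  stopifnot(metric %in% c("fa", "md", "ad", "rd"))
  subj <- unique(profiles$subject_id)
  nodes <- sort(unique(profiles$node))
  out <- matrix(NA_real_, length(subj), length(nodes),
                dimnames = list(subj, NULL))
  pos <- cbind(match(profiles$subject_id, subj), match(profiles$node, nodes))
  out[pos] <- profiles[[metric]]
  out
}

# Equal-variance (or Welch) two-sample t statistics per column, vectorized.
# Returns list(t, df, p). Zero pooled variance gives t = 0, p = 1.
.col_ttest <- function(A, B, var_equal = TRUE) {
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2L, stats::var); vb <- apply(B, 2L, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- ifelse(se > 0, (ma - mb) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t), df), 1)
  list(t = t, df = df, p = p, degenerate = se <= 0)
}

#' Node-wise independent-sample t-test between two groups
#'
#' Two-sided two-sample t-test at every node on the subject-level node
#' values, equal-variance by default (`var_equal = FALSE` gives Welch).
#'
#' @param profiles_a,profiles_b either subjects-by-nodes matrices (see
#'   [node_matrix()]) or long-format profile tables, one group each.
#' @param metric metric name, required when passing long tables.
#' @param var_equal pool the variance (default TRUE).
#' @return list with per-node vectors `t`, `p`, and `df`.
#' @export
nodewise_ttest <- function(profiles_a, profiles_b, metric = NULL,
                           var_equal = TRUE) {
  A <- if (is.data.frame(profiles_a)) node_matrix(profiles_a, metric)
       else as.matrix(profiles_a)
  B <- if (is.data.frame(profiles_b)) node_matrix(profiles_b, metric)
       else as.matrix(profiles_b)
  if (nrow(A) < 2L || nrow(B) < 2L)
    stop("stats_error: need at least 2 subjects per group", call. = FALSE)
  if (ncol(A) != ncol(B))
    stop("stats_error: groups disagree on node count", call. = FALSE)
  r <- .col_ttest(A, B, var_equal)
  list(t = r$t, p = r$p, df = r$df)
}

# t statistics for many A-group index sets at once (equal-variance).
# `picks` is an n_perm x na matrix of row indices into Y forming group A.
.perm_tstats <- function(Y, picks, na, nb) {
  n <- na + nb
  tot <- colSums(Y)
  tot2 <- colSums(Y^2)
  P <- matrix(0, nrow(picks), n)
  P[cbind(rep(seq_len(nrow(picks)), ncol(picks)), as.vector(picks))] <- 1
  SA <- P %*% Y
  SA2 <- P %*% (Y^2)
  ma <- SA / na
  mb <- sweep(-SA, 2L, tot, "+") / nb
  ssa <- SA2 - SA^2 / na
  ssb <- sweep(-SA2, 2L, tot2, "+") -
    (sweep(-SA, 2L, tot, "+"))^2 / nb
  sp2 <- (ssa + ssb) / (n - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  tt[!is.finite(tt)] <- 0
  tt
}

#' Node-wise group comparison with family-wise error correction
#'
#' Computes node-wise two-sample t statistics and adjusts the 100-node
#' family for multiple comparison. The default is the permutation max-T
#' procedure: group labels are permuted `n_perm` times, the maximum |t|
#' over nodes is recorded per permutation, and the adjusted p-value of a
#' node is the fraction of the null distribution at or above its observed
#' |t|. When the group sizes admit no more than `n_perm` distinct label
#' splits, all splits are enumerated exactly instead of sampled. The
#' Bonferroni alternative multiplies raw p-values by the node count.
#' Adjusted p-values are floored at the raw p-value.
#'
#' @inheritParams nodewise_ttest
#' @param method "maxT" (permutation, default) or "bonferroni".
#' @param n_perm number of label permutations (default 10000).
#' @param rng_seed integer seed making the permutation draw reproducible.
#' @param alpha significance level for the per-node flags (default 0.05).
#' @return an object of class `group_stats_result` with per-node `t`,
#'   `p_raw`, `p_adj`, logical `sig`, plus `n_a`, `n_b`, `fwe_method`,
#'   `alpha`, `rng_seed` and (for maxT) `n_perm_used` and `exhaustive`.
#' @export
fwe_correct <- function(profiles_a, profiles_b, metric = NULL,
                        method = c("maxT", "bonferroni"), n_perm = 10000L,
                        rng_seed = 1L, alpha = 0.05, var_equal = TRUE) {
  method <- match.arg(method)
  A <- if (is.data.frame(profiles_a)) node_matrix(profiles_a, metric)
       else as.matrix(profiles_a)
  B <- if (is.data.frame(profiles_b)) node_matrix(profiles_b, metric)
       else as.matrix(profiles_b)
  na <- nrow(A); nb <- nrow(B)
  if (na < 2L && nb < 2L)
    stop("stats_error: both groups have a single subject", call. = FALSE)
  if (na < 2L || nb < 2L)
    stop("stats_error: need at least 2 subjects per group", call. = FALSE)
  obs <- .col_ttest(A, B, var_equal)
  n_nodes <- ncol(A)
  exhaustive <- FALSE
  n_used <- 0L
  if (method == "bonferroni") {
    p_adj <- pmin(1, n_nodes * obs$p)
  } else {
    if (n_perm < 100L)
      warning("n_perm < 100 gives a very coarse null distribution")
    Y <- rbind(A, B)
    n <- na + nb
    n_splits <- choose(n, na)
    if (n_splits <= n_perm) {
      picks <- t(utils::combn(n, na))
      exhaustive <- TRUE
    } else {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(rng_seed)
      picks <- t(replicate(n_perm, sample.int(n, na)))
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
    n_used <- nrow(picks)
    tt <- .perm_tstats(Y, picks, na, nb)
    max_t <- apply(abs(tt), 1L, max)
    p_adj <- vapply(abs(obs$t), function(ti) mean(max_t >= ti - 1e-12),
                    numeric(1L))
    if (!exhaustive)
      p_adj <- (p_adj * n_used + 1) / (n_used + 1)  # guard against p = 0
  }
  p_adj <- pmin(1, pmax(p_adj, obs$p))
  structure(list(t = obs$t, p_raw = obs$p, p_adj = p_adj,
                 sig = p_adj < alpha, df = obs$df,
                 n_a = na, n_b = nb, fwe_method = method, alpha = alpha,
                 rng_seed = rng_seed, n_perm_used = n_used,
                 exhaustive = exhaustive),
            class = "group_stats_result")
}

#' @export
print.group_stats_result <- function(x, ...) {
  cat(sprintf("group_stats_result (%s): %d nodes, %d significant at alpha = %g (n = %d vs %d)\n",
              x$fwe_method, length(x$t), sum(x$sig), x$alpha, x$n_a, x$n_b))
  invisible(x)
}

#' Group summary table of tract-mean diffusion metrics
#'
#' For every (group, tract, hemisphere, metric) cell, the subject-level
#' tract mean (average over all nodes) is summarized as mean +/- SD across
#' subjects, printed to 2 decimal places. A metric is star-marked when more
#' than `min_sig_nodes` nodes are FWE-significant for that tract and
#' metric in the supplied stats results.
#'
#' @param profiles long-format profile table for all subjects and groups.
#' @param stats_results named list of `group_stats_result`, with names
#'   "tract|hemisphere|metric" (see [run_group()]); may be NULL.
#' @param min_sig_nodes star threshold on the FWE-significant node count
#'   (default 10: a metric is marked when significant at more than 10
#'   nodes).
#' @param scale named multipliers applied per metric before formatting
#'   (default prints diffusivities in 1e-3 mm^2/s units).
#' @return data frame with columns group, tract, hemisphere, metric,
#'   mean, sd, n_sig_nodes, significant, cell.
#' @export
summarize_table <- function(profiles, stats_results = NULL,
                            min_sig_nodes = 10L,
                            scale = c(fa = 1, md = 1e3, ad = 1e3, rd = 1e3)) {
  rows <- list()
  combos <- unique(profiles[, c("group", "tract", "hemisphere")])
  for (i in seq_len(nrow(combos))) {
    g <- combos$group[i]; tr <- combos$tract[i]; h <- combos$hemisphere[i]
    sub <- profiles[profiles$group == g & profiles$tract == tr &
                      profiles$hemisphere == h, ]
    for (metric in c("fa", "md", "ad", "rd")) {
      means <- tapply(sub[[metric]], sub$subject_id, mean, na.rm = TRUE)
      mu <- mean(means) * scale[[metric]]
      sdv <- if (length(means) > 1L) stats::sd(means) * scale[[metric]] else 0
      key <- paste(tr, h, metric, sep = "|")
      nsig <- if (!is.null(stats_results) && !is.null(stats_results[[key]]))
        sum(stats_results[[key]]$sig) else 0L
      star <- nsig > min_sig_nodes
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, tract = tr, hemisphere = h, metric = metric,
        mean = mu, sd = sdv, n_sig_nodes = nsig, significant = star,
        cell = sprintf("%.2f ± %.2f%s", mu, sdv, if (star) "*" else ""),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
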