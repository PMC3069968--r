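#' Two-by-two repeated-measures ANOVA on ROI summaries
#'
#' Classical mixed-design sums-of-squares decomposition for a design with
#' one between-subjects factor (GROUP, 2 levels) and one within-subjects
#' factor (TIME, 2 levels): the GROUP effect is tested against the
#' between-subject (subjects-within-groups) mean square, TIME and
#' GROUP x TIME against the within-subject residual. With n = 10 subjects
#' per group the interaction test has df (1, 18). Sphericity is moot with
#' two within-subject levels.
#'
#' @param table data frame with columns \code{subject}, \code{group},
#'   \code{time}, \code{value}; every subject must have both timepoints
#' @return an \code{anova_result}: per effect (GROUP, TIME, GROUPxTIME)
#'   the F value, df pair and p value, plus cell means and SEMs
#' @export
rm_anova_2x2 <- function(table) {
  req <- c("subject", "group", "time", "value")
  assert_that(all(req %in% names(table)), "table missing required columns")
  table$subject <- as.character(table$subject)
  table$group <- as.character(table$group)
  table$time <- as.character(table$time)
  glev <- sort(unique(table$group)); tlev <- sort(unique(table$time))
  if (length(glev) != 2 || length(tlev) != 2)
    stop_ischemri("design must have exactly 2 groups and 2 timepoints",
                  "ischemri_design")
  counts <- table(table$subject, table$time)
  if (any(counts != 1))
    stop_ischemri("every subject needs exactly one value per timepoint",
                  "ischemri_design")
  subj_group <- unique(table[, c("subject", "group")])
  if (anyDuplicated(subj_group$subject))
    stop_ischemri("a subject appears in both groups", "ischemri_design")

  y <- table$value
  M <- mean(y)
  A <- tapply(y, table$group, mean)          # group means
  Tm <- tapply(y, table$time, mean)          # time means
  C <- tapply(y, list(table$group, table$time), mean)
  S <- tapply(y, table$subject, mean)        # subject means
  n_g <- table(subj_group$group)             # subjects per group
  N <- sum(n_g)
  t_n <- length(tlev)

  ss_group <- t_n * sum(n_g * (A[glev] - M)^2)
  ss_subj <- t_n * sum((S[subj_group$subject] - A[subj_group$group])^2)
  ss_time <- N * sum((Tm - M)^2)
  ss_int <- sum(outer(as.numeric(n_g[glev]), rep(1, t_n)) *
                (C[glev, tlev, drop = FALSE] -
                 outer(A[glev], rep(1, t_n)) -
                 outer(rep(1, 2), Tm[tlev]) + M)^2)
  cell_of <- C[cbind(table$group, table$time)]
  subj_of <- S[table$subject]
  grp_of <- A[table$group]
  ss_err <- sum((y - cell_of - subj_of + grp_of)^2)

  df_group <- 1L; df_subj <- as.integer(N - 2)
  df_time <- 1L; df_err <- as.integer(N - 2)
  msw <- function(ss, df) if (df > 0) ss / df else NA_real_
  f_of <- function(ss, df, ms_err, df_err) {
    ms <- ss / df
    f <- if (ms_err > 0) ms / ms_err else { if (ss <= 1e-300) 0 else Inf }
    p <- if (is.finite(f)) stats::pf(f, df, df_err, lower.tail = FALSE) else 0
    list(F = f, df1 = df, df2 = df_err, p = p)
  }
  ms_subj <- msw(ss_subj, df_subj)
  ms_err <- msw(ss_err, df_err)
  eff <- list(
    GROUP = f_of(ss_group, df_group, ms_subj, df_subj),
    TIME = f_of(ss_time, df_time, ms_err, df_err),
    `GROUPxTIME` = f_of(ss_int, df_time, ms_err, df_err)
  )
  cells <- data.frame(
    group = rep(glev, each = t_n), time = rep(tlev, 2),
    mean = as.numeric(t(C[glev, tlev])),
    sem = as.numeric(t(tapply(y, list(table$group, table$time), stats::sd)
                       [glev, tlev] / sqrt(as.numeric(n_g[glev])))),
    stringsAsFactors = FALSE
  )
  structure(list(effects = eff, cells = cells,
                 ss = c(group = ss_group, subjects = ss_subj,
                        time = ss_time, interaction = ss_int,
                        error = ss_err)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Mixed-design 2x2 repeated-measures ANOVA\n")
  for (e in names(x$effects)) {
    f <- x$effects[[e]]
    cat(sprintf("  %-11s F(%d,%d) = %8.3f, p = %.5g\n",
                e, f$df1, f$df2, f$F, f$p))
  }
  invisible(x)
}

#' Two-sided Student t comparison of two samples
#'
#' Pooled-variance unpaired t or difference-based paired t, with the
#' degenerate conventions the pipeline relies on: identical constant
#' samples give t = 0, p = 1; a constant non-zero paired difference is
#' flagged degenerate.
#'
#' @param a,b numeric vectors (equal length if paired)
#' @param paired logical
#' @return list with \code{t}, \code{df}, \code{p}, \code{degenerate}
#' @export
group_compare <- function(a, b, paired = FALSE) {
  assert_that(length(a) >= 2 && length(b) >= 2, "need >= 2 values per group")
  if (paired) {
    assert_that(length(a) == length(b), "paired samples need equal lengths")
    d <- b - a
    if (stats::sd(d) == 0) {
      if (mean(d) == 0)
        return(list(t = 0, df = length(d) - 1L, p = 1, degenerate = TRUE))
      return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0,
                  degenerate = TRUE))
    }
    tt <- stats::t.test(b, a, paired = TRUE)
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b))
        return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                    degenerate = TRUE))
      return(list(t = sign(mean(b) - mean(a)) * Inf,
                  df = length(a) + length(b) - 2L, p = 0, degenerate = TRUE))
    }
    tt <- stats::t.test(b, a, var.equal = TRUE)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

## t statistics for all sign patterns at once. D: N x V difference matrix,
## S: P x N matrix of +/-1. Sign flips leave sum(d^2) unchanged, so the
## per-permutation variance follows from the permuted mean alone.
signflip_t <- function(D, S) {
  N <- nrow(D)
  Mn <- (S %*% D) / N                      # P x V permuted means
  ssq <- matrix(colSums(D^2), nrow(S), ncol(D), byrow = TRUE)
  varr <- (ssq - N * Mn^2) / (N - 1)
  se <- sqrt(pmax(varr, 0) / N)
  t <- Mn / se
  t[se == 0 & Mn == 0] <- 0
  t[se == 0 & Mn > 0] <- Inf
  t[se == 0 & Mn < 0] <- -Inf
  t
}

#' Voxelwise paired change test with max-statistic permutation correction
#'
#' One-sample t test per voxel on per-subject difference maps (e.g.
#' 24 h - 2 h normalized CBF), with family-wise error control by
#' sign-flipping permutation of the subject difference maps and the
#' image-wide maximum statistic (the nonparametric multiple-comparison
#' framework of Nichols & Holmes). The null is built exhaustively
#' (all 2^N sign patterns) when N <= 12, otherwise from \code{n_perm}
#' seeded random flips. One-sided per direction: \code{"increase"} tests
#' 24 h > 2 h, \code{"decrease"} the reverse.
#'
#' @param diff_maps list of \code{parameter_map}s, or an N x V matrix /
#'   list of arrays of per-subject difference maps
#' @param mask logical analysis mask (required for matrix input; otherwise
#'   the intersection of the maps' validity masks)
#' @param direction \code{"increase"} or \code{"decrease"}
#' @param n_perm number of random permutations when not exhaustive
#' @param seed seed for the random flips
#' @param alpha significance level for the significance mask
#' @return a \code{permutation_result}: statistic map, FWER-corrected p
#'   map, significance mask, permutation count, direction
#' @export
voxelwise_change_test <- function(diff_maps, mask = NULL,
                                  direction = c("increase", "decrease"),
                                  n_perm = 10000L, seed = 1L, alpha = 0.05) {
  direction <- match.arg(direction)
  if (is.matrix(diff_maps)) {
    assert_that(!is.null(mask), "matrix input requires a mask")
    D <- diff_maps
    mask <- as_volume(mask)
  } else {
    maps <- diff_maps
    vals <- lapply(maps, function(m) if (inherits(m, "parameter_map")) m else
                                     list(values = as_volume(m), mask = is.finite(as_volume(m))))
    common <- Reduce(`&`, lapply(vals, `[[`, "mask"))
    if (!is.null(mask)) common <- common & as_volume(mask)
    if (!any(common))
      stop_ischemri("non-overlapping validity masks", "ischemri_mask")
    mask <- common
    D <- do.call(rbind, lapply(vals, function(m) m$values[mask]))
  }
  N <- nrow(D)
  if (N < 3) stop_ischemri("need at least 3 subjects", "ischemri_subjects")
  if (direction == "decrease") D <- -D

  exhaustive <- N <= 12
  if (exhaustive) {
    P <- 2^N
    ## row 1 of expand.grid is the identity (all +1)
    S <- unname(as.matrix(expand.grid(rep(list(c(1, -1)), N))))
  } else {
    P <- as.integer(n_perm)
    set.seed(derive_seed(seed, 7L))
    S <- matrix(sample(c(1, -1), (P - 1) * N, replace = TRUE), P - 1, N)
    S <- rbind(rep(1, N), S)
  }
  Tm <- signflip_t(D, S)
  t_obs <- Tm[1, ]
  maxstat <- apply(Tm, 1, max)
  ## corrected p: proportion of permutations whose maximum >= observed
  ord <- sort(maxstat)
  p_corr <- (P - findInterval(t_obs, ord, left.open = TRUE)) / P
  stat_map <- map_from_vector(t_obs, mask)
  p_map <- map_from_vector(p_corr, mask)
  sig <- map_from_vector(p_corr < alpha, mask, fill = FALSE) > 0
  structure(list(stat = stat_map, p_corrected = p_map, significant = sig,
                 mask = mask, n_perm = P, exhaustive = exhaustive,
                 direction = direction, alpha = alpha, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result %s: %d perms%s, %d voxels, %d significant at alpha=%.2g>\n",
              x$direction, x$n_perm, if (x$exhaustive) " (exhaustive)" else "",
              sum(x$mask), sum(x$significant), x$alpha))
  invisible(x)
}
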