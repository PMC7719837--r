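# Within-subjects statistical battery: balanced two-way repeated-measures
# ANOVA with per-effect subject-interaction error terms, Shaffer's
# sequentially rejective multiple-comparison procedure, simple-effect
# follow-ups via paired t tests, Mann-Whitney U (exact by enumeration for
# small tie-free samples), and the variance-ratio-gated Student/Welch t.

#' Balanced two-way repeated-measures ANOVA
#'
#' Full within-subjects decomposition of a complete, balanced
#' subject x condition x familiarity table. Each effect is tested against
#' its own subject-interaction error term (condition against
#' condition x subject, and so on); no sphericity correction is applied, so
#' with a = 3 conditions, b = 2 familiarity levels and n = 14 subjects the
#' degrees of freedom are (2, 26), (1, 13) and (2, 26).
#'
#' @param cell_table Data frame with columns `subject`, `condition`,
#'   `familiarity` and one value per cell (column `value_col`).
#' @param value_col Name of the value column (default `"value_ms"`).
#' @return Object of class `rm_anova`: list with `effects` (data frame:
#'   effect, ss, df1, df2, ms, error_ss, error_ms, f, p,
#'   partial_eta_sq), `subject_ss`, `total_ss`, `residual_ss` and a
#'   `degenerate` flag (zero error variance; F reported as `NA` rather
#'   than masked).
#' @export
rm_anova_2way <- function(cell_table, value_col = "value_ms") {
  needed <- c("subject", "condition", "familiarity", value_col)
  missing <- setdiff(needed, names(cell_table))
  if (length(missing)) {
    stop("rm_anova_2way: missing column(s): ", paste(missing, collapse = ", "))
  }
  subj <- factor(cell_table$subject)
  a_f <- factor(cell_table$condition)
  b_f <- factor(cell_table$familiarity)
  n <- nlevels(subj); a <- nlevels(a_f); b <- nlevels(b_f)
  if (n < 2L) stop("rm_anova_2way: need at least 2 subjects")
  if (nrow(cell_table) != n * a * b ||
      any(table(subj, a_f, b_f) != 1L)) {
    stop("rm_anova_2way: table must be complete and balanced ",
         "(exactly one value per subject x condition x familiarity cell)")
  }
  y <- cell_table[[value_col]]
  if (any(!is.finite(y))) stop("rm_anova_2way: non-finite values")

  gm <- mean(y)
  m_s <- tapply(y, subj, mean)
  m_a <- tapply(y, a_f, mean)
  m_b <- tapply(y, b_f, mean)
  m_ab <- tapply(y, list(a_f, b_f), mean)
  m_as <- tapply(y, list(a_f, subj), mean)
  m_bs <- tapply(y, list(b_f, subj), mean)

  ss_total <- sum((y - gm)^2)
  ss_s <- a * b * sum((m_s - gm)^2)
  ss_a <- b * n * sum((m_a - gm)^2)
  ss_b <- a * n * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + gm)^2)
  ss_as <- b * sum((m_as - outer(m_a, rep(1, n)) -
                      outer(rep(1, a), m_s) + gm)^2)
  ss_bs <- a * sum((m_bs - outer(m_b, rep(1, n)) -
                      outer(rep(1, b), m_s) + gm)^2)
  ss_abs <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs
  ss_abs <- max(ss_abs, 0)

  df_a <- a - 1; df_b <- b - 1; df_ab <- df_a * df_b
  df_as <- df_a * (n - 1); df_bs <- df_b * (n - 1)
  df_abs <- df_ab * (n - 1)

  eff <- data.frame(
    effect = c("condition", "familiarity", "interaction"),
    ss = c(ss_a, ss_b, ss_ab),
    df1 = c(df_a, df_b, df_ab),
    df2 = c(df_as, df_bs, df_abs),
    error_ss = c(ss_as, ss_bs, ss_abs),
    stringsAsFactors = FALSE)
  eff$ms <- eff$ss / eff$df1
  eff$error_ms <- eff$error_ss / eff$df2
  scale <- max(ss_total, .Machine$double.eps)
  degenerate <- eff$error_ms <= 1e-12 * scale
  eff$f <- ifelse(degenerate, NA_real_, eff$ms / eff$error_ms)
  eff$p <- ifelse(is.na(eff$f), NA_real_,
                  stats::pf(eff$f, eff$df1, eff$df2, lower.tail = FALSE))
  eff$partial_eta_sq <- eff$ss / (eff$ss + eff$error_ss)
  eff <- eff[c("effect", "ss", "df1", "df2", "ms", "error_ss", "error_ms",
               "f", "p", "partial_eta_sq")]
  structure(list(effects = eff, subject_ss = ss_s, total_ss = ss_total,
                 residual_ss = ss_abs, n_subjects = n, a = a, b = b,
                 degenerate = any(degenerate)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA (", x$n_subjects, " subjects, ",
      x$a, " x ", x$b, " within-subject design)\n\n", sep = "")
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-12s F(%d, %d) = %.4f, p = %.4g\n", eff$effect[i],
                eff$df1[i], eff$df2[i], eff$f[i], eff$p[i]))
  }
  if (x$degenerate) cat("  [degenerate: zero error variance]\n")
  invisible(x)
}

# All partitions of the integer k (descending parts), recursively.
tg_integer_partitions <- function(k, max_part = k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(k, max_part))) {
    for (rest in tg_integer_partitions(k - p, p)) {
      out[[length(out) + 1L]] <- c(p, rest)
    }
  }
  out
}

#' Shaffer critical denominators for all-pairwise comparisons of k means
#'
#' `t_i` is the maximum number of pairwise-equality hypotheses that can be
#' simultaneously true once `i - 1` have been found false. A configuration
#' of equalities among k means is a partition of the means into equal-value
#' blocks, under which `sum(choose(block_size, 2))` hypotheses are true;
#' the achievable counts are enumerated exactly over partitions of k.
#'
#' @param k_means Number of means compared (k >= 2); the family has
#'   `m = k(k-1)/2` hypotheses.
#' @return Integer vector `t_1 ... t_m`; e.g. `(3, 1, 1)` for k = 3.
#' @export
shaffer_constants <- function(k_means) {
  if (k_means < 2L) stop("shaffer_constants: k_means must be >= 2")
  m <- k_means * (k_means - 1) / 2
  counts <- sort(unique(vapply(tg_integer_partitions(k_means),
                               function(p) sum(choose(p, 2)), numeric(1))))
  vapply(seq_len(m), function(i) {
    as.integer(max(counts[counts <= m - i + 1]))
  }, integer(1))
}

#' Shaffer sequentially rejective multiple-comparison procedure
#'
#' Orders the raw p-values ascending and rejects while
#' `p_(i) <= alpha / t_i` (with `t_i` from [shaffer_constants()]); the
#' procedure stops at the first failure and retains everything after it.
#'
#' @param p_values Raw p-values for all `k(k-1)/2` pairwise comparisons.
#' @param k_means Number of means in the family.
#' @param alpha Family-wise significance level.
#' @param labels Optional comparison labels.
#' @return Data frame in input order: `comparison`, `p_raw`, `rank`,
#'   `t_denominator`, `critical_alpha`, `reject`.
#' @export
shaffer_pairwise <- function(p_values, k_means, alpha = 0.05,
                             labels = NULL) {
  m <- k_means * (k_means - 1) / 2
  if (length(p_values) != m) {
    stop("shaffer_pairwise: expected ", m, " p-values for k = ", k_means,
         " means, got ", length(p_values))
  }
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("shaffer_pairwise: p-values must lie in [0, 1]")
  }
  if (is.null(labels)) labels <- paste0("H", seq_len(m))
  t_i <- shaffer_constants(k_means)
  ord <- order(p_values)
  crit <- alpha / t_i
  ok <- p_values[ord] <= crit
  reject_sorted <- cumprod(ok) == 1 # stop at first failure
  out <- data.frame(comparison = labels, p_raw = p_values,
                    rank = NA_integer_, t_denominator = NA_integer_,
                    critical_alpha = NA_real_, reject = NA,
                    stringsAsFactors = FALSE)
  out$rank[ord] <- seq_len(m)
  out$t_denominator[ord] <- t_i
  out$critical_alpha[ord] <- crit
  out$reject[ord] <- reject_sorted
  out
}

#' Paired t test on two matched vectors
#'
#' @param x,y Matched samples (same subjects, same order).
#' @return List: `t`, `df`, `p`, `mean_diff`, `degenerate` (zero-variance
#'   differences).
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("paired_t_test: need two equal-length vectors, n >= 2")
  }
  d <- x - y
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = n - 1, p = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Simple-effect and main-effect pairwise follow-ups
#'
#' Three decision families over the cell table, all via paired t tests on
#' subject-level values: (i) within each familiarity level, the three
#' condition comparisons, Shaffer-corrected with k = 3; (ii) within each
#' condition, the single familiar-vs-unfamiliar comparison (family of one,
#' no correction); (iii) the condition main-effect comparisons on
#' subject-level condition means (averaged over familiarity),
#' Shaffer-corrected with k = 3.
#'
#' @param cell_table As for [rm_anova_2way()].
#' @param alpha Family-wise significance level per family.
#' @param value_col Name of the value column.
#' @return List of data frames: `condition_within_familiarity`,
#'   `familiarity_within_condition`, `condition_main`. Each row carries
#'   the family, comparison label, t statistic, df, raw p and decision.
#' @export
simple_effects <- function(cell_table, alpha = 0.05,
                           value_col = "value_ms") {
  subjects <- sort(unique(cell_table$subject))
  val <- function(cond, fam) {
    rows <- cell_table[cell_table$condition == cond &
                         cell_table$familiarity == fam, ]
    rows[[value_col]][match(subjects, rows$subject)]
  }
  cond_pairs <- utils::combn(tg_conditions(), 2, simplify = FALSE)

  shaffer_family <- function(family, pairs, value_of) {
    tests <- lapply(pairs, function(pr) {
      tt <- paired_t_test(value_of(pr[1]), value_of(pr[2]))
      data.frame(family = family,
                 comparison = paste(pr[1], "vs", pr[2]),
                 t = tt$t, df = tt$df, p_raw = tt$p,
                 stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, tests)
    dec <- shaffer_pairwise(tests$p_raw, k_means = 3, alpha = alpha,
                            labels = tests$comparison)
    cbind(tests, dec[c("rank", "t_denominator", "critical_alpha", "reject")])
  }

  cwf <- do.call(rbind, lapply(tg_familiarity(), function(fam) {
    shaffer_family(paste0("conditions | ", fam), cond_pairs,
                   function(cond) val(cond, fam))
  }))

  fwc <- do.call(rbind, lapply(tg_conditions(), function(cond) {
    tt <- paired_t_test(val(cond, "familiar"), val(cond, "unfamiliar"))
    data.frame(family = paste0("familiarity | ", cond),
               comparison = "familiar vs unfamiliar",
               t = tt$t, df = tt$df, p_raw = tt$p,
               rank = 1L, t_denominator = 1L, critical_alpha = alpha,
               reject = tt$p <= alpha, stringsAsFactors = FALSE)
  }))

  cond_mean <- function(cond) {
    (val(cond, "familiar") + val(cond, "unfamiliar")) / 2
  }
  main <- shaffer_family("conditions (main effect)", cond_pairs, cond_mean)

  rownames(cwf) <- rownames(fwc) <- rownames(main) <- NULL
  list(condition_within_familiarity = cwf,
       familiarity_within_condition = fwc,
       condition_main = main)
}

#' Mann-Whitney U test
#'
#' U counts pairwise wins with half credit for ties. The p-value is exact
#' (full enumeration of group assignments) when both samples have at most
#' 8 observations and there are no ties; otherwise a normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param a,b Numeric samples.
#' @param mode `"auto"` (default), `"exact"` (forced enumeration) or
#'   `"normal"`.
#' @return List: `U_a`, `U_b`, `statistic` (= `U_a`), `p`, `method`,
#'   `ties`. Always `U_a + U_b = n_a * n_b`.
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stop("mann_whitney_u: empty sample")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  ties <- anyDuplicated(pooled) > 0L

  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = n_a <= 8 && n_b <= 8 && !ties)
  if (use_exact) {
    u_of <- function(idx) {
      ra <- r[idx]
      sum(ra) - length(idx) * (length(idx) + 1) / 2
    }
    dist_u <- utils::combn(n, n_a, u_of)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(dist_u <= u_a + eps),
                        mean(dist_u >= u_a - eps)))
    method <- "exact enumeration"
  } else {
    mu <- n_a * n_b / 2
    tie_tab <- table(pooled)
    sigma2 <- n_a * n_b / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u_a - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation (tie-corrected, continuity-corrected)"
  }
  list(U_a = u_a, U_b = u_b, statistic = u_a, p = min(p, 1),
       method = method, ties = ties)
}

#' Variance-ratio-gated two-sample t test
#'
#' First a two-sided F test of equal variances at `gate_alpha`; if it
#' rejects, Welch's t with Satterthwaite degrees of freedom, otherwise
#' Student's t with pooled variance. The branch taken is recorded.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param gate_alpha Significance level of the variance gate.
#' @return List: `branch` (`"welch"` or `"student"`), `f_statistic`,
#'   `f_p`, `t`, `df`, `p`, `mean_a`, `mean_b`, `degenerate` (both
#'   variances zero).
#' @export
variance_gated_t_test <- function(a, b, gate_alpha = 0.05) {
  n_a <- length(a); n_b <- length(b)
  if (n_a < 2L || n_b < 2L) {
    stop("variance_gated_t_test: need n >= 2 per sample")
  }
  v_a <- stats::var(a); v_b <- stats::var(b)
  if (v_a == 0 && v_b == 0) {
    eq <- mean(a) == mean(b)
    return(list(branch = NA_character_, f_statistic = NA_real_,
                f_p = NA_real_, t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = NA_real_, p = if (eq) 1 else 0,
                mean_a = mean(a), mean_b = mean(b), degenerate = TRUE))
  }
  f_stat <- v_a / v_b
  f_p <- if (v_b == 0) 0 else {
    pr <- stats::pf(f_stat, n_a - 1, n_b - 1)
    min(1, 2 * min(pr, 1 - pr))
  }
  if (f_p <= gate_alpha) {
    branch <- "welch"
    se2_a <- v_a / n_a; se2_b <- v_b / n_b
    se <- sqrt(se2_a + se2_b)
    df <- (se2_a + se2_b)^2 /
      (se2_a^2 / (n_a - 1) + se2_b^2 / (n_b - 1))
  } else {
    branch <- "student"
    sp2 <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  }
  t <- (mean(a) - mean(b)) / se
  list(branch = branch, f_statistic = f_stat, f_p = f_p, t = t, df = df,
       p = 2 * stats::pt(-abs(t), df), mean_a = mean(a), mean_b = mean(b),
       degenerate = FALSE)
}
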