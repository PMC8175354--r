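#' Circle sizes of one ego
#'
#' Counts the nominations of one student by Dunbar circle. `C1` is the
#' inner-circle count (edges of the requested sign and direction with
#' |weight| = 2, i.e. "best friend" / "worst enemy"); `C2` is the cumulative
#' count over both intensity levels. With `scope = "intra_group"` only
#' alters in the ego's own roster group are counted.
#'
#' @param net a [signed_network()].
#' @param ego a node id present in `net`.
#' @param sign `"positive"` or `"negative"`.
#' @param scope `"all"` or `"intra_group"` (the latter needs `roster`).
#' @param direction `"out"` (nominations given) or `"in"` (received).
#' @param roster roster supplying group labels for `scope = "intra_group"`.
#' @return named numeric vector `c(C1 = , C2 = )` with `C2 >= C1`.
#' @export
circle_sizes <- function(net, ego, sign = c("positive", "negative"),
                         scope = c("all", "intra_group"),
                         direction = c("out", "in"), roster = NULL) {
  sign <- match.arg(sign)
  scope <- match.arg(scope)
  direction <- match.arg(direction)
  if (!ego %in% net$nodes) stop_validation("unknown ego: ", ego)
  e <- net$edges
  e <- if (sign == "positive") e[e$weight > 0, ] else e[e$weight < 0, ]
  if (direction == "out") {
    e <- e[e$from == ego, ]
    alters <- e$to
  } else {
    e <- e[e$to == ego, ]
    alters <- e$from
  }
  if (scope == "intra_group") {
    if (is.null(roster)) stop_validation("intra_group scope requires a roster")
    own <- roster$group[match(ego, roster$id)]
    keep <- roster$group[match(alters, roster$id)] %in% own
    keep[is.na(keep)] <- FALSE
    e <- e[keep, ]
  }
  c(C1 = sum(abs(e$weight) == 2), C2 = nrow(e))
}

#' The circle-structure parameter mu
#'
#' For an ego with cumulative circle sizes `C1` (inner) and `C2` (inner +
#' outer), the ring sizes are `l1 = C1` and `l2 = C2 - C1` and
#' `mu = log(l2 / l1)` (natural logarithm). Under the resource-allocation
#' model of layered personal networks with unit cost increments between
#' layers, consecutive ring sizes scale as `e^mu`, so with exactly two
#' elicited layers the fitted scaling parameter reduces to this closed form.
#' `mu > 0` is the canonical top-light circle structure (each circle about
#' 3 times the previous gives `mu ~ 0.7`); `mu < 0` means most friends are
#' already in the inner circle. `mu` is undefined (returned as `NA`) when
#' `C1 = 0` or `C2 = C1`, where the log-ratio is singular; such egos are
#' excluded from summaries and counted separately.
#'
#' @param C1,C2 nonnegative circle counts, `C2 >= C1` (vectorized).
#' @return numeric vector of `mu` values with `NA` where undefined.
#' @examples
#' compute_mu(5, 15)   # log 2, the ratio-3 circle structure
#' compute_mu(4, 8)    # 0: rings of equal size
#' compute_mu(4, 6)    # negative: top-heavy inner circle
#' @export
compute_mu <- function(C1, C2) {
  if (any(C1 < 0 | C2 < 0)) stop_validation("circle sizes must be nonnegative")
  if (any(C2 < C1)) stop_validation("C2 must be >= C1 (circles are cumulative)")
  ifelse(C1 >= 1 & C2 > C1, log((C2 - C1) / C1), NA_real_)
}

#' The in-degree analogue rho of mu
#'
#' Same statistic as [compute_mu()], computed on received nominations, i.e.
#' on the in-degree circle sizes of the ego.
#'
#' @inheritParams circle_sizes
#' @return a single `rho` value, `NA` where undefined.
#' @export
compute_rho <- function(net, ego, roster = NULL, scope = c("all", "intra_group"),
                        sign = c("positive", "negative")) {
  cs <- circle_sizes(net, ego, sign = match.arg(sign), scope = match.arg(scope),
                     direction = "in", roster = roster)
  unname(compute_mu(cs["C1"], cs["C2"]))
}

#' Per-student circle profiles for a whole wave
#'
#' Computes `C1`, `C2` and `mu` for every eligible ego in one call. When a
#' roster and wave are supplied, egos are the wave's participants (isolated
#' participants get zero counts); nominated non-participants are never egos.
#'
#' @inheritParams circle_sizes
#' @param wave optional wave number (1 or 2) used with `roster` to select
#'   participant egos.
#' @return data frame with columns `ego`, `group`, `wave`, `scope`, `sign`,
#'   `direction`, `C1`, `C2`, `mu`.
#' @export
circle_profiles <- function(net, roster = NULL, wave = NA,
                            sign = c("positive", "negative"),
                            scope = c("all", "intra_group"),
                            direction = c("out", "in")) {
  sign <- match.arg(sign)
  scope <- match.arg(scope)
  direction <- match.arg(direction)
  if (!is.null(roster) && !is.na(wave)) {
    egos <- intersect(net$nodes, roster$id[roster[[paste0("wave", wave)]]])
  } else {
    egos <- net$nodes
  }
  e <- net$edges
  e <- if (sign == "positive") e[e$weight > 0, ] else e[e$weight < 0, ]
  anchor <- if (direction == "out") e$from else e$to
  alter <- if (direction == "out") e$to else e$from
  if (scope == "intra_group") {
    if (is.null(roster)) stop_validation("intra_group scope requires a roster")
    keep <- roster$group[match(anchor, roster$id)] ==
      roster$group[match(alter, roster$id)]
    keep[is.na(keep)] <- FALSE
    e <- e[keep, ]; anchor <- anchor[keep]
  }
  f <- factor(anchor, levels = egos)
  C2 <- as.integer(table(f))
  C1 <- integer(length(egos))
  inner <- abs(e$weight) == 2
  if (any(inner)) {
    tab <- table(factor(anchor[inner], levels = egos))
    C1 <- as.integer(tab)
  }
  grp <- if (!is.null(roster)) roster$group[match(egos, roster$id)] else NA_character_
  data.frame(ego = egos, group = grp, wave = wave, scope = scope, sign = sign,
             direction = direction, C1 = C1, C2 = C2,
             mu = compute_mu(C1, C2), stringsAsFactors = FALSE)
}

#' Per-student change in mu between the two waves
#'
#' Computes `delta = mu_wave2 - mu_wave1` for every student who participated
#' in both waves and has a defined `mu` in both. Counts of students excluded
#' for each reason are attached as attribute `"eligibility"`.
#'
#' @param pair a [network_pair()].
#' @param scope,sign,direction as in [circle_profiles()].
#' @return data frame `ego`, `group`, `mu_wave1`, `mu_wave2`, `delta`.
#' @export
mu_increment <- function(pair, scope = "all", sign = "positive",
                         direction = "out") {
  stopifnot(inherits(pair, "network_pair"))
  p1 <- circle_profiles(pair$wave1, pair$roster, wave = 1, sign = sign,
                        scope = scope, direction = direction)
  p2 <- circle_profiles(pair$wave2, pair$roster, wave = 2, sign = sign,
                        scope = scope, direction = direction)
  common <- intersect(p1$ego, p2$ego)
  m1 <- p1$mu[match(common, p1$ego)]
  m2 <- p2$mu[match(common, p2$ego)]
  defined <- !is.na(m1) & !is.na(m2)
  out <- data.frame(ego = common[defined],
                    group = p1$group[match(common[defined], p1$ego)],
                    mu_wave1 = m1[defined], mu_wave2 = m2[defined],
                    delta = m2[defined] - m1[defined],
                    stringsAsFactors = FALSE)
  attr(out, "eligibility") <- c(
    common_participants = length(common),
    undefined_wave1 = sum(is.na(m1)),
    undefined_wave2 = sum(is.na(m2)),
    eligible = sum(defined)
  )
  out
}

#' Group-level mu summary table
#'
#' Per-group (and TOTAL) unweighted mean and sample SD of `mu` in each wave
#' and of the per-student increment, in the layout of the study's summary
#' table. Cells with no defined value are reported as `NA` (missing, never
#' zero); single-value cells report `sd = 0` and are flagged by `n = 1`.
#' Egos with undefined `mu` are excluded from means and counted in the
#' `n_excluded` columns.
#'
#' @param profiles_w1,profiles_w2 outputs of [circle_profiles()] for the two
#'   waves.
#' @param increments output of [mu_increment()].
#' @return data frame with one row per group plus `"TOTAL"`.
#' @export
group_mu_table <- function(profiles_w1, profiles_w2, increments) {
  groups <- sort(unique(c(profiles_w1$group, profiles_w2$group)))
  cell <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    c(mean = if (n) mean(v) else NA_real_,
      sd = if (n >= 2) stats::sd(v) else if (n == 1) 0 else NA_real_,
      n = n)
  }
  row_for <- function(sel1, sel2, seli) {
    w1 <- cell(profiles_w1$mu[sel1]); w2 <- cell(profiles_w2$mu[sel2])
    inc <- cell(increments$delta[seli])
    data.frame(mean_wave1 = w1["mean"], sd_wave1 = w1["sd"], n_wave1 = w1["n"],
               n_excluded_wave1 = sum(sel1) - w1["n"],
               mean_wave2 = w2["mean"], sd_wave2 = w2["sd"], n_wave2 = w2["n"],
               n_excluded_wave2 = sum(sel2) - w2["n"],
               mean_increment = inc["mean"], sd_increment = inc["sd"],
               n_increment = inc["n"], row.names = NULL)
  }
  rows <- lapply(groups, function(g) {
    row_for(profiles_w1$group %in% g, profiles_w2$group %in% g,
            increments$group %in% g)
  })
  rows <- c(rows, list(row_for(rep(TRUE, nrow(profiles_w1)),
                               rep(TRUE, nrow(profiles_w2)),
                               rep(TRUE, nrow(increments)))))
  out <- do.call(rbind, rows)
  cbind(data.frame(group = c(groups, "TOTAL"), stringsAsFactors = FALSE), out)
}

#' Statistical tests on the per-group mu increments
#'
#' The pipeline's increment-testing stage: per group a Shapiro-Wilk
#' normality test and a one-sample t test of the mean increment against 0,
#' then a one-way ANOVA across groups and Tukey HSD pairwise comparisons.
#' Groups with fewer than `min_n` increments are skipped with a reason;
#' zero-variance groups are flagged and their t statistic reported as `NA`.
#'
#' @param increments output of [mu_increment()] (columns `group`, `delta`).
#' @param min_n minimum group size for testing (default 3, the Shapiro-Wilk
#'   minimum).
#' @return object of class `increment_tests`: list with data frames
#'   `per_group` (Shapiro-Wilk and t-test results), `tukey`, list `anova`,
#'   and data frame `skipped`.
#' @export
increment_tests <- function(increments, min_n = 3) {
  stopifnot(min_n >= 3)
  split_d <- split(increments$delta, increments$group)
  skipped <- data.frame(group = character(), reason = character(),
                        stringsAsFactors = FALSE)
  rows <- list()
  eligible <- character()
  for (g in names(split_d)) {
    d <- split_d[[g]]
    if (length(d) < min_n) {
      skipped <- rbind(skipped, data.frame(group = g,
        reason = sprintf("n = %d < %d", length(d), min_n)))
      next
    }
    eligible <- c(eligible, g)
    zero_var <- stats::sd(d) == 0
    sw <- if (zero_var) list(statistic = NA_real_, p.value = NA_real_)
          else stats::shapiro.test(d)
    tt <- if (zero_var) list(statistic = NA_real_, parameter = length(d) - 1,
                             p.value = NA_real_)
          else stats::t.test(d, mu = 0)
    rows[[g]] <- data.frame(
      group = g, n = length(d), mean = mean(d), sd = stats::sd(d),
      shapiro_W = unname(sw$statistic), shapiro_p = sw$p.value,
      t = unname(tt$statistic), t_df = unname(tt$parameter), t_p = tt$p.value,
      zero_variance = zero_var, stringsAsFactors = FALSE)
  }
  per_group <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL
  anova_res <- NULL; tukey <- NULL
  if (length(eligible) >= 2) {
    dd <- increments[increments$group %in% eligible, ]
    dd$group <- factor(dd$group)
    if (stats::sd(dd$delta) == 0) {
      anova_res <- list(F = NA_real_, df_between = length(eligible) - 1,
                        df_within = nrow(dd) - length(eligible),
                        p = NA_real_, zero_variance = TRUE)
    } else {
      fit <- stats::aov(delta ~ group, data = dd)
      s <- summary(fit)[[1]]
      anova_res <- list(F = s[["F value"]][1],
                        df_between = s[["Df"]][1], df_within = s[["Df"]][2],
                        p = s[["Pr(>F)"]][1], zero_variance = FALSE)
      th <- stats::TukeyHSD(fit)$group
      tukey <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                          lwr = th[, "lwr"], upr = th[, "upr"],
                          p_adj = th[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE)
    }
  }
  structure(list(per_group = per_group, anova = anova_res, tukey = tukey,
                 skipped = skipped),
            class = "increment_tests")
}

#' @export
print.increment_tests <- function(x, ...) {
  cat("Per-group mu-increment tests\n")
  if (!is.null(x$per_group)) print(x$per_group, digits = 3)
  if (!is.null(x$anova)) {
    cat(sprintf("ANOVA: F(%d,%d) = %.3f, p = %.3g\n", x$anova$df_between,
                x$anova$df_within, x$anova$F, x$anova$p))
  }
  if (nrow(x$skipped)) {
    cat("Skipped:", paste(x$skipped$group, x$skipped$reason, sep = ": ",
                          collapse = "; "), "\n")
  }
  invisible(x)
}
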