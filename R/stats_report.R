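#' Ordinary least-squares fit of a single predictor
#'
#' Thin wrapper around [stats::lm()] returning the quantities the
#' reporting layer needs: slope, intercept, R-squared and the two-sided t
#' test of the slope with n - 2 degrees of freedom. A constant response
#' (zero total sum of squares) is reported as slope 0, R-squared 0,
#' p-value 1.
#'
#' @param x Predictor (n >= 3, not constant).
#' @param y Response, same length.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`, `significant` (p < 0.05).
#' @export
linear_fit <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("`x` is constant; slope is undefined")
  if (stats::sd(y) == 0) {
    return(tibble::tibble(slope = 0, intercept = y[1], r_squared = 0,
                          p_value = 1, n = n, significant = FALSE))
  }
  fit <- stats::lm(y ~ x)
  s <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      # exact synthetic fits are legitimate inputs here
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  p <- s$coefficients["x", "Pr(>|t|)"]
  tibble::tibble(slope = unname(stats::coef(fit)["x"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = s$r.squared, p_value = p, n = n,
                 significant = p < 0.05)
}

#' Regress pools on a treatment-level quality indicator
#'
#' Per pool and occasion, per-jar pool values are regressed on the value
#' of a litter-quality indicator (litter C:N or a DRIFT compound ratio)
#' attached to each treatment. The mineral-N amended treatment is excluded
#' by default -- its indicator does not capture the amendment -- as is any
#' treatment with an undefined indicator (the unamended control).
#'
#' @param partition Partition table from [partition_pools()].
#' @param indicator Named numeric vector mapping treatment labels to
#'   indicator values.
#' @param pools Pool columns to regress.
#' @param exclude_labels Treatments left out of every regression.
#' @return Tibble: `pool`, `month`, plus the [linear_fit()] columns.
#' @export
regress_pools <- function(partition, indicator,
                          pools = c("bulk_total", "bulk_new", "bulk_old",
                                    "poc_total", "poc_new", "poc_old",
                                    "maoc_total", "maoc_new", "maoc_old"),
                          exclude_labels = "CN124N") {
  keep <- !(partition$treatment %in% exclude_labels) &
    partition$treatment %in% names(indicator)
  data <- partition[keep, ]
  data$x <- unname(indicator[data$treatment])
  data <- data[!is.na(data$x), ]
  if (length(unique(data$treatment)) < 3)
    stop("fewer than 3 treatments left after exclusions")
  grid <- expand.grid(pool = intersect(pools, names(data)),
                      month = sort(unique(data$month)),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    rows <- data[data$month == grid$month[i], ]
    dplyr::bind_cols(tibble::tibble(pool = grid$pool[i],
                                    month = grid$month[i]),
                     linear_fit(rows$x, rows[[grid$pool[i]]]))
  })
  dplyr::bind_rows(res)
}

#' One-way ANOVA with Tukey HSD and compact letters
#'
#' Fits a one-way ANOVA, computes all pairwise Tukey HSD comparisons
#' (studentized-range adjusted p-values, via [stats::TukeyHSD()]), and
#' derives a compact letter display with the insert-and-absorb algorithm:
#' groups are ordered by descending mean; every significant pair splits
#' the letter columns containing both members; redundant (absorbed)
#' columns are removed; letters are assigned in order of first
#' appearance. Two groups share a letter if and only if their adjusted
#' p-value is at least `alpha`. The procedure is deterministic.
#'
#' @param value Numeric response.
#' @param group Grouping factor or character vector (>= 2 groups, >= 2
#'   observations each).
#' @param alpha Significance level for both the letters and the pairwise
#'   flags.
#' @return A `tukey_letters` object: `letters` (named character vector,
#'   ordered by descending group mean), `pairwise` (tibble of pairwise
#'   differences and adjusted p-values), `means`, `anova_f`, `anova_p`,
#'   `alpha`.
#' @export
anova_tukey <- function(value, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("need >= 2 observations per group")
  if (all(tapply(value, group, stats::sd) == 0))
    stop("zero within-group variance in every group")
  fit <- stats::aov(value ~ group)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pairwise <- tibble::tibble(group1 = pairs[, 1], group2 = pairs[, 2],
                             diff = tk[, "diff"], p_adj = tk[, "p adj"])
  means <- sort(tapply(value, group, mean), decreasing = TRUE)
  letters <- cld_insert_absorb(names(means), pairwise, alpha)
  structure(list(letters = letters, pairwise = pairwise, means = means,
                 anova_f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
                 alpha = alpha),
            class = "tukey_letters")
}

# Insert-and-absorb compact letter display. `ordered_groups` must be in
# the display order (descending mean); `pairwise` holds adjusted p-values.
cld_insert_absorb <- function(ordered_groups, pairwise, alpha) {
  cols <- list(ordered_groups)
  sig <- pairwise[pairwise$p_adj < alpha, , drop = FALSE]
  if (nrow(sig) > 0) {
    for (i in seq_len(nrow(sig))) {
      g1 <- sig$group1[i]; g2 <- sig$group2[i]
      hit <- which(vapply(cols, function(cl) g1 %in% cl && g2 %in% cl,
                          logical(1)))
      for (j in hit) {
        both <- cols[[j]]
        cols[[j]] <- setdiff(both, g1)
        cols[[length(cols) + 1L]] <- setdiff(both, g2)
      }
      # absorb: drop any column that is a subset of another
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) for (b in seq_along(cols)) {
        if (a != b && keep[a] && keep[b] &&
            all(cols[[a]] %in% cols[[b]]) &&
            !(all(cols[[b]] %in% cols[[a]]) && a < b))
          keep[a] <- FALSE
      }
      cols <- cols[keep]
    }
  }
  # order columns by the position of their first group, assign letters
  first_pos <- vapply(cols, function(cl)
    min(match(cl, ordered_groups)), numeric(1))
  cols <- cols[order(first_pos)]
  out <- stats::setNames(rep("", length(ordered_groups)), ordered_groups)
  for (i in seq_along(cols))
    for (g in cols[[i]]) out[g] <- paste0(out[g], letters[i])
  out
}

#' @export
print.tukey_letters <- function(x, ...) {
  cat("One-way ANOVA: F =", signif(x$anova_f, 4), ", p =",
      signif(x$anova_p, 4), "\nTukey HSD letters (alpha =", x$alpha, "):\n")
  for (g in names(x$letters))
    cat(sprintf("  %-10s %8.3f  %s\n", g, x$means[g], x$letters[g]))
  invisible(x)
}

#' Numeric residual-normality note
#'
#' Advisory diagnostic replacing visual QQ inspection: sample skewness
#' and excess kurtosis of model residuals, with a plain-language note.
#' Never gates any result. Fewer than 4 residuals are declared not
#' assessable.
#'
#' @param model A fitted `lm`/`aov` model, or a numeric residual vector.
#' @return One-row tibble: `n`, `skewness`, `kurtosis_excess`,
#'   `assessable`, `note`.
#' @export
residual_normality_note <- function(model) {
  r <- if (is.numeric(model)) model else stats::residuals(model)
  r <- r[is.finite(r)]
  n <- length(r)
  if (n < 4) {
    return(tibble::tibble(n = n, skewness = NA_real_,
                          kurtosis_excess = NA_real_, assessable = FALSE,
                          note = "too few residuals to assess normality"))
  }
  m <- mean(r); s2 <- mean((r - m)^2)
  skew <- mean((r - m)^3) / s2^1.5
  kurt <- mean((r - m)^4) / s2^2 - 3
  note <- if (abs(skew) < 1 && abs(kurt) < 2)
    "residuals approximately symmetric and light-tailed"
  else "residuals deviate noticeably from normality; interpret p-values with care"
  tibble::tibble(n = n, skewness = skew, kurtosis_excess = kurt,
                 assessable = TRUE, note = note)
}
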