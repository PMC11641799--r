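#' Fisher's LSD pairwise comparisons for one trait
#'
#' One-way ANOVA across the requested groups yields the pooled error mean
#' square (MSE, df = N - k); each pair of groups is then compared with the
#' unprotected LSD t statistic
#' `t = (m_i - m_j) / sqrt(MSE * (1/n_i + 1/n_j))` and a two-sided p-value
#' from the t distribution on N - k df. No multiplicity correction is
#' applied (LSD is the unprotected procedure); the omnibus F test is
#' reported alongside so users can protect it themselves.
#'
#' Groups are the `stage:lineage:condition` cells of the trait table unless
#' a `group` column is already present. With MSE = 0 (all values identical
#' within groups) the comparison is degenerate: p is 1 for zero differences
#' and 0 otherwise, flagged in the `degenerate` column.
#'
#' @param table trait table (columns trait, stage, lineage, condition,
#'   replicate, value — or trait, group, value).
#' @param trait trait name to test (may be omitted if the table holds one
#'   trait).
#' @param groups optional character vector restricting/ordering the groups.
#' @param alpha significance level used for the compact letter display.
#' @return list of class `lsd_result`: `pairs` (data.frame: group_i,
#'   group_j, diff, se, t, df, p, degenerate), `means`, `n`, `mse`, `df`,
#'   `f_stat`, `f_p`, `letters` (compact letter display).
#' @export
lsd_test <- function(table, trait = NULL, groups = NULL, alpha = 0.05) {
  df <- as.data.frame(table)
  if (!"group" %in% names(df)) {
    need <- c("stage", "lineage", "condition")
    if (!all(need %in% names(df))) {
      stop("trait table needs either a 'group' column or stage/lineage/condition")
    }
    df$group <- paste(df$stage, df$lineage, df$condition, sep = ":")
  }
  if (!is.null(trait)) {
    if (!"trait" %in% names(df)) stop("no 'trait' column in table")
    df <- df[df$trait == trait, , drop = FALSE]
    if (nrow(df) == 0) stop("trait not found: ", trait)
  }
  if (!is.null(groups)) {
    missing <- setdiff(groups, df$group)
    if (length(missing)) stop("missing groups: ", paste(missing, collapse = ", "))
    df <- df[df$group %in% groups, , drop = FALSE]
    df$group <- factor(df$group, levels = groups)
  } else {
    df$group <- factor(df$group)
  }
  if (anyNA(df$value) || any(!is.finite(df$value))) stop("trait values must be finite")
  n_g <- table(df$group)
  if (nlevels(df$group) < 2) stop("need at least 2 groups")
  if (any(n_g < 2)) stop("every group needs >= 2 replicates")

  k <- nlevels(df$group)
  N <- nrow(df)
  means <- tapply(df$value, df$group, mean)
  ss_within <- sum(tapply(df$value, df$group, function(v) sum((v - mean(v))^2)))
  df_err <- N - k
  mse <- ss_within / df_err
  ss_between <- sum(n_g * (means - mean(df$value))^2)
  ms_between <- ss_between / (k - 1)
  f_stat <- if (mse > 0) ms_between / mse else
    ifelse(ss_between > 0, Inf, NaN)
  f_p <- if (is.finite(f_stat)) stats::pf(f_stat, k - 1, df_err, lower.tail = FALSE)
         else if (is.infinite(f_stat)) 0 else NA_real_

  combos <- utils::combn(levels(df$group), 2)
  pairs <- data.frame(group_i = combos[1, ], group_j = combos[2, ],
                      stringsAsFactors = FALSE)
  pairs$diff <- means[pairs$group_i] - means[pairs$group_j]
  pairs$se <- sqrt(mse * (1 / n_g[pairs$group_i] + 1 / n_g[pairs$group_j]))
  degenerate <- mse <= 0
  if (degenerate) {
    pairs$t <- ifelse(pairs$diff == 0, 0, Inf * sign(pairs$diff))
    pairs$p <- ifelse(pairs$diff == 0, 1, 0)
  } else {
    pairs$t <- pairs$diff / pairs$se
    pairs$p <- 2 * stats::pt(-abs(pairs$t), df_err)
  }
  pairs$df <- df_err
  pairs$degenerate <- degenerate
  rownames(pairs) <- NULL

  out <- list(pairs = pairs, means = means, n = as.vector(n_g),
              mse = mse, df = df_err, f_stat = f_stat, f_p = f_p,
              letters = compact_letters(means, pairs, alpha = alpha))
  class(out) <- "lsd_result"
  out
}

#' @export
print.lsd_result <- function(x, ...) {
  cat("Fisher's LSD (", length(x$means), " groups, MSE = ",
      signif(x$mse, 4), ", df = ", x$df, ")\n", sep = "")
  cat("omnibus F =", signif(x$f_stat, 4), ", p =", signif(x$f_p, 4), "\n")
  print(x$pairs, digits = 4)
  invisible(x)
}

# greedy compact letter display: groups visited in descending mean order,
# joined to the first existing letter whose members are all non-different at
# alpha; ties in means resolved by the original group order
compact_letters <- function(means, pairs, alpha = 0.05) {
  ord <- names(sort(means, decreasing = TRUE))
  p_of <- function(a, b) {
    hit <- (pairs$group_i == a & pairs$group_j == b) |
           (pairs$group_i == b & pairs$group_j == a)
    pairs$p[hit][1]
  }
  groups_in <- list()
  for (g in ord) {
    placed <- FALSE
    for (li in seq_along(groups_in)) {
      if (all(vapply(groups_in[[li]], function(m) p_of(g, m) >= alpha,
                     logical(1)))) {
        groups_in[[li]] <- c(groups_in[[li]], g)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups_in[[length(groups_in) + 1]] <- g
  }
  lab <- stats::setNames(rep("", length(means)), names(means))
  for (li in seq_along(groups_in)) {
    for (g in groups_in[[li]]) lab[g] <- paste0(lab[g], letters[li])
  }
  lab
}

#' Classify a trait as weaken or strengthen from its P4 reaction norm
#'
#' Compares the stress response of the two lineages on re-exposure. With
#' `D_CK = mean(P1CK-P4S) - mean(P1CK-P4CK)` (naive lineage response) and
#' `D_S = mean(P1S-P4S) - mean(P1S-P4CK)` (primed lineage response), and L
#' the LSD p-value for P1CK-P4S vs P1S-P4S (pooled MSE over the four P4
#' groups):
#' \itemize{
#'   \item weaken: both responses negative, the primed drop smaller
#'     (`D_S > D_CK`) and L < alpha — suppression attenuated by priming;
#'   \item strengthen: both responses positive, the primed rise larger
#'     (`D_S > D_CK`) and L < alpha — induction amplified by priming;
#'   \item unclassified otherwise (no response, or inconsistent direction).
#' }
#'
#' @param table trait table covering stage P4 for both lineages and
#'   conditions.
#' @param trait trait name.
#' @param alpha significance level for the lineage contrast (default 0.05).
#' @return data.frame row: trait, label, delta_ck, delta_s, lsd_p.
#' @export
classify_trait <- function(table, trait, alpha = 0.05) {
  df <- as.data.frame(table)
  df <- df[df$trait == trait & df$stage == "P4", , drop = FALSE]
  cells <- expand.grid(lineage = c("P1CK", "P1S"), condition = c("CK", "S"),
                       stringsAsFactors = FALSE)
  have <- unique(df[, c("lineage", "condition")])
  ok <- merge(cells, have)
  if (nrow(ok) < 4) {
    stop("trait '", trait,
         "' must be measured at P4 for both lineages under both conditions")
  }
  g <- function(l, c) df$value[df$lineage == l & df$condition == c]
  delta_ck <- mean(g("P1CK", "S")) - mean(g("P1CK", "CK"))
  delta_s <- mean(g("P1S", "S")) - mean(g("P1S", "CK"))
  lsd <- lsd_test(df, groups = paste("P4", c("P1CK", "P1S", "P1CK", "P1S"),
                                     c("CK", "CK", "S", "S"), sep = ":"))
  pick <- (lsd$pairs$group_i == "P4:P1CK:S" & lsd$pairs$group_j == "P4:P1S:S") |
          (lsd$pairs$group_i == "P4:P1S:S" & lsd$pairs$group_j == "P4:P1CK:S")
  lsd_p <- lsd$pairs$p[pick][1]
  label <- "unclassified"
  if (delta_ck < 0 && delta_s < 0 && delta_s > delta_ck && lsd_p < alpha) {
    label <- "weaken"
  } else if (delta_ck > 0 && delta_s > 0 && delta_s > delta_ck && lsd_p < alpha) {
    label <- "strengthen"
  }
  data.frame(trait = trait, label = label, delta_ck = delta_ck,
             delta_s = delta_s, lsd_p = lsd_p, stringsAsFactors = FALSE)
}

#' Classify every trait in a table
#'
#' @inheritParams classify_trait
#' @return data.frame with one [classify_trait()] row per trait.
#' @export
classify_traits <- function(table, alpha = 0.05) {
  traits <- unique(as.data.frame(table)$trait)
  do.call(rbind, lapply(traits, function(tr) classify_trait(table, tr, alpha)))
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target_treated - Ct_ref_treated) -
#'         (Ct_target_control - Ct_ref_control)`; the relative expression of
#' the target in the treated sample, normalized to the reference gene and
#' the control sample, is `2^-ddCt`. Vectorized over all arguments.
#'
#' @param ct_target_treated,ct_ref_treated Ct values in the treated sample.
#' @param ct_target_control,ct_ref_control Ct values in the control sample.
#' @return fold change(s) `2^-ddCt`.
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  args <- list(ct_target_treated, ct_ref_treated,
               ct_target_control, ct_ref_control)
  if (any(vapply(args, function(x) anyNA(x) || any(!is.finite(x)), logical(1)))) {
    stop("Ct values must be finite")
  }
  dd <- (ct_target_treated - ct_ref_treated) -
        (ct_target_control - ct_ref_control)
  2^(-dd)
}
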