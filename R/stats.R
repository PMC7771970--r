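#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' The group-statistics backbone of the morphometric reporting: a one-way
#' ANOVA across (genotype x condition) groups followed by all-pairs Tukey
#' HSD with adjusted p-values from the studentized-range distribution
#' (Tukey-Kramer for unbalanced designs), plus a compact letter display at
#' the given significance level.
#'
#' Degenerate inputs with zero within-group variance are reported with an
#' explicit `degenerate` flag: pairs with distinct means get adjusted
#' p = 0, identical means p = 1.
#'
#' @param groups either a named list of numeric vectors, or a data.frame
#'   with columns `value` and `group`.
#' @param alpha significance level for letters.
#' @return object of class `group_comparison`: list with `groups`
#'   (data.frame value/group), `anova` (list `F`, `p`, `df_between`,
#'   `df_within`), `tukey` (data.frame `group1`, `group2`, `diff`, `lwr`,
#'   `upr`, `p_adj`), `letters` (named character), `alpha`, `degenerate`.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  df <- if (is.data.frame(groups)) {
    data.frame(value = groups$value, group = as.character(groups$group))
  } else {
    data.frame(value = unlist(groups, use.names = FALSE),
               group = rep(names(groups), lengths(groups)))
  }
  df <- df[complete.cases(df), ]
  counts <- table(df$group)
  if (length(counts) < 2L) stop("need at least 2 groups")
  if (any(counts < 2L))
    stop("every group needs at least 2 observations; offending: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  df$group <- factor(df$group, levels = unique(df$group))
  lev <- levels(df$group)
  gm <- tapply(df$value, df$group, mean)
  resid_ss <- sum((df$value - gm[df$group])^2)
  npairs <- utils::combn(lev, 2L)
  degenerate <- resid_ss < 1e-12 * max(1, sum(df$value^2))
  if (degenerate) {
    dif <- gm[npairs[2L, ]] - gm[npairs[1L, ]]
    p <- ifelse(abs(dif) > 0, 0, 1)
    tk <- data.frame(group1 = npairs[1L, ], group2 = npairs[2L, ],
                     diff = as.numeric(dif), lwr = as.numeric(dif),
                     upr = as.numeric(dif), p_adj = as.numeric(p))
    an <- list(F = if (any(p == 0)) Inf else 0,
               p = if (any(p == 0)) 0 else 1,
               df_between = length(lev) - 1L,
               df_within = nrow(df) - length(lev))
  } else {
    fit <- aov(value ~ group, data = df)
    at <- anova(fit)
    an <- list(F = at$`F value`[1L], p = at$`Pr(>F)`[1L],
               df_between = at$Df[1L], df_within = at$Df[2L])
    th <- TukeyHSD(fit, conf.level = 1 - alpha)$group
    nm <- strsplit(rownames(th), "-", fixed = TRUE)
    tk <- data.frame(group1 = vapply(nm, `[`, "", 2L),
                     group2 = vapply(nm, `[`, "", 1L),
                     diff = th[, "diff"], lwr = th[, "lwr"],
                     upr = th[, "upr"], p_adj = th[, "p adj"],
                     row.names = NULL)
  }
  cmp <- structure(list(groups = df, anova = an, tukey = tk,
                        letters = NULL, alpha = alpha,
                        degenerate = degenerate),
                   class = "group_comparison")
  cmp$letters <- letter_display(cmp)
  cmp
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: %d groups, F = %.4g (df %d/%d), p = %.3g%s\n",
              nlevels(x$groups$group), x$anova$F, x$anova$df_between,
              x$anova$df_within, x$anova$p,
              if (x$degenerate) " [degenerate: zero within-group variance]"
              else ""))
  lt <- x$letters
  cat(paste(sprintf("  %s: %s", names(lt), lt), collapse = "\n"), "\n")
  invisible(x)
}

#' Compact letter display (insert-and-absorb)
#'
#' Letters such that two groups share at least one letter iff their
#' pairwise adjusted p-value is at or above `alpha`. Starts with a single
#' letter containing all groups; each significant pair splits every letter
#' containing both; redundant (absorbed) letters are removed; letters are
#' named 'a', 'b', ... in group order.
#'
#' @param comparison a [anova_tukey()] result, or a symmetric matrix of
#'   pairwise p-values with group names on both dimnames.
#' @param alpha significance level (taken from the comparison when given).
#' @return named character vector: group -> letter string.
#' @export
letter_display <- function(comparison, alpha = 0.05) {
  if (inherits(comparison, "group_comparison")) {
    alpha <- comparison$alpha
    lev <- levels(comparison$groups$group)
    P <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
    tk <- comparison$tukey
    for (i in seq_len(nrow(tk))) {
      P[tk$group1[i], tk$group2[i]] <- tk$p_adj[i]
      P[tk$group2[i], tk$group1[i]] <- tk$p_adj[i]
    }
  } else {
    P <- as.matrix(comparison)
    if (is.null(rownames(P))) {
      rownames(P) <- colnames(P) <- paste0("g", seq_len(nrow(P)))
    }
    lev <- rownames(P)
  }
  sets <- list(lev)
  pairs <- utils::combn(length(lev), 2L)
  for (c0 in seq_len(ncol(pairs))) {
    gi <- lev[pairs[1L, c0]]; gj <- lev[pairs[2L, c0]]
    if (P[gi, gj] >= alpha) next
    newsets <- list()
    for (s in sets) {
      if (gi %in% s && gj %in% s) {
        newsets <- c(newsets, list(setdiff(s, gj)), list(setdiff(s, gi)))
      } else newsets <- c(newsets, list(s))
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(newsets))
    for (i in seq_along(newsets)) for (j in seq_along(newsets)) {
      if (i != j && keep[j] &&
          all(newsets[[i]] %in% newsets[[j]]) &&
          (length(newsets[[i]]) < length(newsets[[j]]) || i > j))
        keep[i] <- FALSE
    }
    sets <- newsets[keep]
  }
  ord <- order(vapply(sets, function(s) min(match(s, lev)), numeric(1L)))
  sets <- sets[ord]
  out <- setNames(rep("", length(lev)), lev)
  for (i in seq_along(sets))
    out[sets[[i]]] <- paste0(out[sets[[i]]], letters[i])
  out
}

#' Fold-change summaries against a baseline condition
#'
#' Per condition, the ratio of mean meristem area and mean cell number to
#' the baseline condition, and the percent change of the mean median cell
#' area — the summary used to express how much larger the domed meristem
#' is than the vegetative one.
#'
#' @param records a list of [summarize_apex()] records, or a data.frame
#'   with columns `condition`, `meristem_area`, `cell_number`,
#'   `median_cell_area`.
#' @param baseline baseline condition label.
#' @return data.frame with one row per condition: `condition`, `n`,
#'   `area_ratio`, `cell_number_ratio`, `median_cell_area_change_pct`;
#'   attribute `per_apex` keeps the per-apex table.
#' @export
fold_changes <- function(records, baseline) {
  df <- if (is.data.frame(records)) records else
    do.call(rbind, lapply(records, as.data.frame))
  if (!baseline %in% df$condition)
    stop("baseline condition '", baseline, "' absent from records")
  base <- df[df$condition == baseline, ]
  out <- do.call(rbind, lapply(split(df, df$condition), function(g) {
    data.frame(condition = g$condition[1L], n = nrow(g),
               area_ratio = mean(g$meristem_area) / mean(base$meristem_area),
               cell_number_ratio = mean(g$cell_number) / mean(base$cell_number),
               median_cell_area_change_pct =
                 100 * (mean(g$median_cell_area) /
                          mean(base$median_cell_area) - 1))
  }))
  rownames(out) <- NULL
  structure(out[order(out$condition != baseline, out$condition), ],
            per_apex = df)
}
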