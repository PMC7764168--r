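#' One-way analysis of variance
#'
#' Classical between/within variance decomposition on grouped replicate
#' measurements, via [stats::aov()].
#'
#' @param data A data frame with columns `group` and `value` (e.g. from
#'   [generate_replicate_groups()]), at least 2 groups with at least 2
#'   replicates each.
#' @return A list of class `"oneway_fit"` with `F`, `p`, `df` (between,
#'   within) and the underlying `aov` fit.
#' @examples
#' d <- generate_replicate_groups(c(a = 1, b = 1.2, c = 3), sd = 0.2,
#'                                n_per_group = 5, seed = 1)
#' anova_oneway(d)
#' @export
anova_oneway <- function(data) {
  data <- validate_grouped(data)
  if (diff(range(data$value)) == 0)
    stop("degenerate data: all values identical, F undefined",
         call. = FALSE)
  fit <- stats::aov(value ~ group, data = data)
  tab <- summary(fit)[[1]]
  structure(list(F = tab["group", "F value"],
                 p = tab["group", "Pr(>F)"],
                 df = c(between = tab["group", "Df"],
                        within = tab["Residuals", "Df"]),
                 aov = fit),
            class = "oneway_fit")
}

#' @export
print.oneway_fit <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df[1], ", ", x$df[2], ") = ",
      format(x$F, digits = 4), ", p = ", format.pval(x$p, digits = 3),
      "\n", sep = "")
  invisible(x)
}

validate_grouped <- function(data) {
  if (!is.data.frame(data) || !all(c("group", "value") %in% names(data)))
    stop("grouped data needs columns 'group' and 'value'", call. = FALSE)
  data$group <- factor(data$group)
  if (nlevels(data$group) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(table(data$group) < 2L))
    stop("need at least 2 replicates per group", call. = FALSE)
  if (any(!is.finite(data$value)))
    stop("values must be finite", call. = FALSE)
  data
}

#' Tukey pairwise comparison with compact letter display
#'
#' Runs Tukey's honestly-significant-difference test on all group pairs
#' (via [stats::TukeyHSD()], which applies the Tukey-Kramer adjustment for
#' unequal group sizes) and summarises the result as significance letters:
#' two groups share a letter exactly when their pairwise comparison is
#' *not* significant at level `alpha`. Letters are assigned with the
#' insert-and-absorb algorithm: start from one letter covering all groups;
#' for every significant pair, split each letter containing both members
#' into two copies (one without each member); finally absorb letters whose
#' group set is contained in another's. Letters are ordered by descending
#' group mean, so "a" marks the highest-mean homogeneous set.
#'
#' @inheritParams anova_oneway
#' @param alpha Familywise significance level, in (0, 1); default 0.05.
#' @return A data frame of class `"letter_display"` with columns `group`,
#'   `mean`, `n`, `letters`, ordered by descending mean; the pairwise
#'   adjusted p-value matrix is in `attr(, "p_matrix")`.
#' @examples
#' d <- generate_replicate_groups(c(lo = 0, mid = 1, hi = 10), sd = 0.4,
#'                                n_per_group = 4, seed = 2)
#' tukey_cld(d)
#' @export
tukey_cld <- function(data, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  data <- validate_grouped(data)
  fit <- anova_oneway(data)
  hsd <- stats::TukeyHSD(fit$aov, conf.level = 1 - alpha)$group
  groups <- levels(data$group)
  k <- length(groups)
  p_mat <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  pair <- strsplit(rownames(hsd), "-", fixed = TRUE)
  for (i in seq_along(pair)) {
    a <- pair[[i]][1]; b <- pair[[i]][2]
    p_mat[a, b] <- p_mat[b, a] <- hsd[i, "p adj"]
  }
  diag(p_mat) <- 1
  means <- tapply(data$value, data$group, mean)
  ord <- order(-means)
  letters_by_group <- cld_insert_absorb(groups[ord],
                                        sig = p_mat[ord, ord, drop = FALSE] <
                                          alpha)
  out <- data.frame(group = groups[ord],
                    mean = as.numeric(means[ord]),
                    n = as.integer(table(data$group)[ord]),
                    letters = letters_by_group[groups[ord]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("letter_display", "data.frame"),
            p_matrix = p_mat, alpha = alpha)
}

# Insert-and-absorb letter assignment. `groups` are ordered (by descending
# mean); `sig` is the logical significant-difference matrix in that order.
# Returns a named character vector of letter strings.
cld_insert_absorb <- function(groups, sig) {
  k <- length(groups)
  cols <- list(groups) # each column = set of groups sharing one letter
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        if (!isTRUE(sig[i, j])) next
        gi <- groups[i]; gj <- groups[j]
        new_cols <- list()
        for (col in cols) {
          if (gi %in% col && gj %in% col) {
            new_cols <- c(new_cols, list(setdiff(col, gi)),
                          list(setdiff(col, gj)))
          } else {
            new_cols <- c(new_cols, list(col))
          }
        }
        # absorb: drop any column whose set is a subset of another's
        keep <- rep(TRUE, length(new_cols))
        for (a in seq_along(new_cols)) {
          for (b in seq_along(new_cols)) {
            if (a != b && keep[b] &&
                all(new_cols[[a]] %in% new_cols[[b]]) &&
                (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
              keep[a] <- FALSE
              break
            }
          }
        }
        cols <- new_cols[keep]
      }
    }
  }
  # order letters by the rank of their best (highest-mean) member
  first_member <- vapply(cols, function(col)
    min(match(col, groups)), numeric(1))
  cols <- cols[order(first_member)]
  if (length(cols) > 26L)
    stop("more than 26 letters needed; too many groups", call. = FALSE)
  lab <- letters[seq_along(cols)]
  out <- vapply(groups, function(g)
    paste(lab[vapply(cols, function(col) g %in% col, logical(1))],
          collapse = ""), character(1))
  names(out) <- groups
  out
}

#' @export
print.letter_display <- function(x, ...) {
  cat("Tukey HSD compact letter display (alpha = ",
      attr(x, "alpha"), ")\n", sep = "")
  print.data.frame(x)
  cat("Groups sharing a letter are not significantly different.\n")
  invisible(x)
}
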