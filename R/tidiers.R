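#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a paired signal test
#'
#' @param x A `paired_signal_test` object from [paired_t_signal()].
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `p_value`, `df`, `mean_diff`,
#'   `n`, `degenerate`.
#' @method tidy paired_signal_test
#' @export
tidy.paired_signal_test <- function(x, ...) {
  tibble(statistic = x$t, p_value = x$p, df = x$df,
         mean_diff = x$mean_diff, n = x$n, degenerate = x$degenerate)
}

#' @rdname tidy.paired_signal_test
#' @method glance paired_signal_test
#' @export
glance.paired_signal_test <- function(x, ...) tidy.paired_signal_test(x, ...)

#' Tidy an entropy contrast
#'
#' @param x An `entropy_contrast` object from [entropy_contrast()].
#' @param ... Unused.
#' @return `tidy()` returns the per-gene entropy tibble with its `group`
#'   column; `glance()` returns a one-row summary (medians, rank-sum
#'   statistic, p, direction).
#' @method tidy entropy_contrast
#' @export
tidy.entropy_contrast <- function(x, ...) x$entropies

#' @rdname tidy.entropy_contrast
#' @method glance entropy_contrast
#' @export
glance.entropy_contrast <- function(x, ...) {
  tibble(median_target = x$median_target,
         median_non_target = x$median_non_target,
         statistic = x$statistic, p_value = x$p,
         direction = x$direction, test = x$test,
         n_dropped = x$n_dropped)
}

#' Tidy a fold comparison
#'
#' @param x A `fold_comparison` object from [pairwise_fold_calls()].
#' @param ... Unused.
#' @return `tidy()` returns the per-gene ratio table; `glance()` a one-row
#'   summary of gained/lost/unchanged counts.
#' @method tidy fold_comparison
#' @export
tidy.fold_comparison <- function(x, ...) x$table

#' @rdname tidy.fold_comparison
#' @method glance fold_comparison
#' @export
glance.fold_comparison <- function(x, ...) {
  tibble(n_gained = length(x$gained), n_lost = length(x$lost),
         n_unchanged = sum(x$table$status == "unchanged"),
         fold = x$fold, pseudo = x$pseudo)
}

#' Tidy a conservation contrast
#'
#' @param x A `conservation_contrast` object from [conservation_contrast()].
#' @param ... Unused.
#' @return `tidy()` returns the per-category fraction table; `glance()` a
#'   one-row summary including the hypergeometric p-value.
#' @method tidy conservation_contrast
#' @export
tidy.conservation_contrast <- function(x, ...) x$fractions

#' @rdname tidy.conservation_contrast
#' @method glance conservation_contrast
#' @export
glance.conservation_contrast <- function(x, ...) {
  tibble(p_value = x$p,
         n_universe = x$counts$universe,
         n_ref_marked = x$counts$ref_marked,
         n_spruce_marked = x$counts$spruce_marked,
         n_joint = x$counts$joint)
}

#' @export
print.paired_signal_test <- function(x, ...) {
  cat("Paired signal test: t =", format(x$t, digits = 4),
      "on", x$df, "df, p =", format(x$p, digits = 4), "\n")
  if (x$degenerate) cat("  (degenerate: zero variance of nonzero differences)\n")
  invisible(x)
}

#' @export
print.entropy_contrast <- function(x, ...) {
  cat("Entropy contrast (", x$test, "):\n", sep = "")
  cat("  median target     =", format(x$median_target, digits = 4), "\n")
  cat("  median non-target =", format(x$median_non_target, digits = 4), "\n")
  cat("  p =", format(x$p, digits = 4), "(", x$direction, ")\n")
  invisible(x)
}

#' @export
print.fold_comparison <- function(x, ...) {
  cat("Fold comparison (threshold ", x$fold, "x): ",
      length(x$gained), " gained, ", length(x$lost), " lost, ",
      sum(x$table$status == "unchanged"), " unchanged\n", sep = "")
  invisible(x)
}

#' @export
print.conservation_contrast <- function(x, ...) {
  cat("Conservation contrast (hypergeometric p =",
      format(x$p, digits = 4), "):\n")
  print(x$fractions)
  invisible(x)
}
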