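#' Ploidy hypothesis
#'
#' Describes an inheritance mode as an ordered list of subgenome ploidies.
#' A single entry denotes polysomic (auto-) inheritance, e.g. `4` for an
#' autotetraploid; several entries denote disomic-within-subgenome
#' (allo-) inheritance, e.g. `c(2, 2)` for an allotetraploid. All
#' subgenomes of one hypothesis must share the same ploidy. The total
#' ploidy `k` is the sum over subgenomes.
#'
#' @param subgenomes Integer vector of per-subgenome ploidies.
#' @return Object of class `ploidy_hypothesis` with elements `subgenomes`
#'   and `k`.
#' @examples
#' ploidy_hypothesis(4)        # autotetraploid
#' ploidy_hypothesis(c(2, 2))  # allotetraploid
#' @export
ploidy_hypothesis <- function(subgenomes) {
  if (inherits(subgenomes, "ploidy_hypothesis")) return(subgenomes)
  subgenomes <- as.integer(subgenomes)
  if (length(subgenomes) < 1L || any(subgenomes < 1L))
    stop("subgenome ploidies must be positive integers")
  if (length(subgenomes) > 1L && length(unique(subgenomes)) > 1L)
    stop("all subgenomes of one hypothesis must have the same ploidy")
  structure(list(subgenomes = subgenomes, k = sum(subgenomes)),
            class = "ploidy_hypothesis")
}

#' @export
print.ploidy_hypothesis <- function(x, ...) {
  cat(sprintf("Ploidy hypothesis: k = %d (%s)\n", x$k,
              if (length(x$subgenomes) == 1L) "polysomic"
              else paste0("subgenomes ",
                          paste(x$subgenomes, collapse = "+"))))
  invisible(x)
}

# normalize a user-supplied list of hypotheses
as_ploidy_list <- function(ploidies) {
  if (inherits(ploidies, "ploidy_hypothesis")) ploidies <- list(ploidies)
  if (!is.list(ploidies)) ploidies <- list(ploidies)
  lapply(ploidies, ploidy_hypothesis)
}
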