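#' Cytotype state vectors
#'
#' The state of all three models is the vector of four cytotype frequencies:
#' `p` (resident mitotype, symbiont-infected), `q` (resident mitotype,
#' uninfected), `r` (novel mitotype, symbiont-infected) and `s` (novel
#' mitotype, uninfected). Components are non-negative and sum to one.
#'
#' The constructor clamps components within `-1e-15` of zero (floating-point
#' guard), renormalizes when the total deviates from one by more than
#' `1e-12`, and refuses states whose total deviates by more than `1e-9` —
#' large deviations indicate a genuine bug rather than roundoff and silently
#' renormalizing them would mask it.
#'
#' @param p,q,r,s Cytotype frequencies.
#' @return A named numeric vector of class `cytotype_state`.
#' @examples
#' cytotype_state(p = 0.28, q = 0.72)
#' @export
cytotype_state <- function(p, q, r = 0, s = 0) {
  x <- c(p = as.double(p), q = as.double(q),
         r = as.double(r), s = as.double(s))
  settle_state(x)
}

#' @rdname cytotype_state
#' @param x A numeric vector of length four (in `p, q, r, s` order).
#' @export
as_cytotype_state <- function(x) {
  if (inherits(x, "cytotype_state")) return(x)
  if (!is.numeric(x) || length(x) != 4L) {
    cyto_abort("A cytotype state needs exactly four frequencies (p, q, r, s).",
               "cytosweep_error_state")
  }
  cytotype_state(x[[1]], x[[2]], x[[3]], x[[4]])
}

# Shared guard applied after every constructed or stepped state.
settle_state <- function(x) {
  if (any(!is.finite(x))) {
    cyto_abort("Cytotype frequencies must be finite.", "cytosweep_error_state")
  }
  x[x < 0 & x > -1e-15] <- 0
  if (any(x < 0)) {
    cyto_abort("Cytotype frequencies must be non-negative.",
               "cytosweep_error_state")
  }
  total <- sum(x)
  if (abs(total - 1) > 1e-9) {
    cyto_abort(
      sprintf("Cytotype frequencies sum to %.12g, not 1.", total),
      "cytosweep_error_conservation")
  }
  if (abs(total - 1) > 1e-12) x <- x / total
  structure(x, class = "cytotype_state")
}

#' Marginal frequencies of a cytotype state
#'
#' `symbiont_freq()` returns the overall symbiont prevalence `p + r`;
#' `mutant_freq()` the overall novel-mitotype frequency `r + s`.
#'
#' @param state A [cytotype_state()].
#' @return A single frequency.
#' @export
symbiont_freq <- function(state) unname(state[[1]] + state[[3]])

#' @rdname symbiont_freq
#' @export
mutant_freq <- function(state) unname(state[[3]] + state[[4]])

#' @export
print.cytotype_state <- function(x, digits = 6, ...) {
  cat("<cytotype_state>  ",
      paste0(names(unclass(x)), " = ", signif(unclass(x), digits),
             collapse = ", "), "\n", sep = "")
  gens <- attr(x, "generations")
  if (!is.null(gens)) cat("  (reached after ", gens, " generations)\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.cytotype_state <- function(x, ...) {
  tibble(p = x[[1]], q = x[[2]], r = x[[3]], s = x[[4]])
}
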