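#' Two-sided Fisher's exact test for one GO term
#'
#' Tests whether a term's annotation count differs between two gene sets via
#' the 2x2 table `[a, totalA - a; b, totalB - b]`. The two-sided p-value
#' follows the usual convention: the sum of hypergeometric probabilities of
#' all tables (with the same margins) no more likely than the observed one.
#'
#' @param a,total_a Term count and total annotated genes in set A.
#' @param b,total_b Term count and total annotated genes in set B.
#' @param alternative Passed to [stats::fisher.test()]; the two-sided
#'   default matches the convention above.
#' @return The p-value.
#' @examples
#' fisher_exact_two_sided(3, 3, 0, 3)  # 0.1
#' @export
fisher_exact_two_sided <- function(a, total_a, b, total_b,
                                   alternative = "two.sided") {
  if (a < 0 || b < 0 || a > total_a || b > total_b) stop("invalid counts")
  if (total_a <= 0 || total_b <= 0) stop("totals must be positive")
  m <- matrix(c(a, total_a - a, b, total_b - b), nrow = 2, byrow = TRUE)
  fisher.test(m, alternative = alternative)$p.value
}

#' Benjamini-Hochberg FDR adjustment with significance flags
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return List with `q` (step-up adjusted values, monotone) and
#'   `significant` (`q <= alpha`).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  q <- p.adjust(p, method = "BH")
  list(q = q, significant = !is.na(q) & q <= alpha)
}

#' Compare GO annotation counts between two gene sets
#'
#' Runs a per-term two-sided Fisher's exact test over the union of terms in
#' the two count tables (a term absent from one table counts 0 there),
#' adjusts across all tested terms by Benjamini-Hochberg, and assigns the
#' conventional direction symbols: `"++"` for terms overrepresented in set
#' A, `"--"` for underrepresented, and `"\u2318"` for terms without a
#' significant difference.
#'
#' @param table_a,table_b Tibbles/data.frames with `term` and `count`.
#' @param total_a,total_b Total annotated genes per set; default to the
#'   table column sums.
#' @param alpha FDR level.
#' @return Tibble with `term`, `count_a`, `count_b`, `total_a`, `total_b`,
#'   `p`, `q`, `significant`, `symbol`, ordered by `q`.
#' @export
compare_go_sets <- function(table_a, table_b, total_a = NULL, total_b = NULL,
                            alpha = 0.05) {
  stopifnot(all(c("term", "count") %in% names(table_a)),
            all(c("term", "count") %in% names(table_b)))
  if (is.null(total_a)) total_a <- sum(table_a$count)
  if (is.null(total_b)) total_b <- sum(table_b$count)
  terms <- union(table_a$term, table_b$term)
  if (!length(terms)) stop("empty term universe")
  a <- table_a$count[match(terms, table_a$term)]
  b <- table_b$count[match(terms, table_b$term)]
  a[is.na(a)] <- 0L
  b[is.na(b)] <- 0L
  # terms annotated in neither set carry no information and are not tested
  present <- a + b > 0L
  terms <- terms[present]
  a <- a[present]
  b <- b[present]
  if (!length(terms)) stop("empty term universe")
  p <- vapply(seq_along(terms), function(i) {
    fisher_exact_two_sided(a[i], total_a, b[i], total_b)
  }, numeric(1))
  adj <- bh_fdr(p, alpha)
  over <- a / total_a > b / total_b
  symbol <- ifelse(!adj$significant, "\u2318", ifelse(over, "++", "--"))
  out <- tibble::tibble(
    term = terms, count_a = a, count_b = b,
    total_a = total_a, total_b = total_b,
    p = p, q = adj$q, significant = adj$significant, symbol = symbol
  )
  out[order(out$q, out$p, out$term), , drop = FALSE]
}
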