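## Mantel permutation test between two species-by-species pairwise
## matrices (temporal overlap vs spatial association).

#' Mantel test between two pairwise species matrices
#'
#' Correlates the upper triangles of two symmetric matrices sharing the
#' same species labels and assesses significance by simultaneous row/column
#' permutation of the second matrix. With `S <= 7` species all `S!` label
#' permutations are enumerated exactly (the identity included), removing
#' Monte-Carlo noise at small community sizes; otherwise `n_perm` random
#' permutations are drawn.
#'
#' @param m1,m2 symmetric numeric matrices with identical dimnames;
#'   diagonals are ignored.
#' @param n_perm random permutations when enumeration is not used
#'   (default 999).
#' @param seed integer seed for the Monte-Carlo branch.
#' @param method correlation on the triangles: `"pearson"` (default) or
#'   `"spearman"` (invariant to monotone rescaling).
#' @param alternative `"greater"` (default; positive association expected)
#'   or `"two.sided"` on `|r|`.
#' @return list with `r`, `p_value`, `n_perm` (permutations actually used),
#'   `exact` (logical), `method`, `alternative`.
#' @export
mantel_test <- function(m1, m2, n_perm = 999, seed = NULL,
                        method = c("pearson", "spearman"),
                        alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (!isTRUE(all.equal(dimnames(m1), dimnames(m2))) ||
      is.null(rownames(m1))) {
    stop("matrices must carry identical species labels in the same order")
  }
  s <- nrow(m1)
  if (s < 4) stop("need at least 4 species for a meaningful Mantel test")
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  if (stats::sd(v1) == 0 || stats::sd(m2[ut]) == 0) {
    stop("constant matrix: correlation undefined")
  }
  stat <- function(mm) stats::cor(v1, mm[ut], method = method)
  r_obs <- stat(m2)
  score <- function(r) if (alternative == "greater") r else abs(r)
  if (s <= 7) {
    perms <- all_permutations(s)
    r_perm <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      stat(m2[p, p])
    }, numeric(1))
    ## exact test: the identity is one of the enumerated relabellings
    p <- mean(score(r_perm) >= score(r_obs) - 1e-12)
    list(r = r_obs, p_value = p, n_perm = nrow(perms), exact = TRUE,
         method = method, alternative = alternative)
  } else {
    if (is.null(seed)) {
      seed <- sample.int(.Machine$integer.max, 1)
      message("mantel_test: seed not supplied, using ", seed)
    }
    r_perm <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        p <- sample.int(s)
        stat(m2[p, p])
      }, numeric(1))
    })
    p <- (1 + sum(score(r_perm) >= score(r_obs) - 1e-12)) / (1 + n_perm)
    list(r = r_obs, p_value = p, n_perm = n_perm, exact = FALSE,
         method = method, alternative = alternative, seed = seed)
  }
}

## all permutations of 1..n as a matrix (n! rows); n <= 7 keeps this small
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (pos in seq_len(n)) {
    block <- sub + (sub >= pos)
    out[row + seq_len(nrow(sub)), ] <-
      cbind(rep.int(pos, nrow(sub)), block)
    row <- row + nrow(sub)
  }
  out
}
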