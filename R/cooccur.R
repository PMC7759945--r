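## Probabilistic spatial co-occurrence over camera stations: for each
## species pair the null model fixes the station totals N1 and N2 and asks,
## hypergeometrically, whether the observed number of shared stations is
## smaller or larger than chance.

#' Build the station-by-species detection matrix
#'
#' @param events event data.frame with `station` and `species` columns.
#' @param stations station ids defining the rows (default: stations present
#'   in `events`); an event at an unknown station is an error.
#' @param species column labels (default: species present, sorted). A
#'   species with no events is allowed only when named explicitly here.
#' @return binary matrix, stations x species; entry 1 when the species has
#'   at least one independent event at the station.
#' @export
build_detection_matrix <- function(events, stations = NULL, species = NULL) {
  if (is.null(stations)) stations <- sort(unique(events$station))
  if (is.null(species)) species <- sort(unique(events$species))
  unknown <- setdiff(unique(events$station), stations)
  if (length(unknown) > 0) {
    stop("events at station(s) not in the station list: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  mat <- matrix(0L, length(stations), length(species),
                dimnames = list(stations, species))
  sel <- events$species %in% species
  idx <- cbind(match(events$station[sel], stations),
               match(events$species[sel], species))
  mat[unique(idx, MARGIN = 1)] <- 1L
  mat
}

#' Probability that two species co-occur at exactly j stations
#'
#' Fixing the number of stations occupied by each species (`N1`, `N2`) out
#' of `N`, the number of shared stations under independent placement is
#' hypergeometric:
#' \deqn{P_j = \binom{N_1}{j}\binom{N-N_1}{N_2-j}\Big/\binom{N}{N_2},}
#' evaluated in log space. Zero outside the support
#' `max(0, N1+N2-N) <= j <= min(N1, N2)`.
#'
#' @param N total stations; `N1`,`N2` stations occupied by each species;
#'   `j` shared stations (vectorised).
#' @return probabilities.
#' @export
#' @examples
#' pj_probability(5, 2, 3, 0:2)  # 0.1 0.6 0.3
pj_probability <- function(N, N1, N2, j) {
  stopifnot(N >= 1, N1 >= 0, N2 >= 0, N1 <= N, N2 <= N)
  stats::dhyper(j, m = N1, n = N - N1, k = N2)
}

#' Tail probabilities of the co-occurrence null model
#'
#' `p_lt` is the probability of sharing fewer stations than observed
#' (`sum of P_j for j < Q_obs`), `p_gt` of sharing more (`j > Q_obs`);
#' together with `P_{Q_obs}` they sum to one.
#'
#' @param N,N1,N2 margins as in [pj_probability()].
#' @param Q_obs observed number of shared stations (must lie in the
#'   support).
#' @return list with `p_lt`, `p_gt`.
#' @export
#' @examples
#' cooccurrence_test(5, 2, 3, 2)  # p_lt = 0.7, p_gt = 0
cooccurrence_test <- function(N, N1, N2, Q_obs) {
  lo <- max(0, N1 + N2 - N); hi <- min(N1, N2)
  if (Q_obs < lo || Q_obs > hi) {
    stop("Q_obs = ", Q_obs, " outside the support [", lo, ", ", hi, "]")
  }
  list(p_lt = stats::phyper(Q_obs - 1, m = N1, n = N - N1, k = N2),
       p_gt = stats::phyper(Q_obs, m = N1, n = N - N1, k = N2,
                            lower.tail = FALSE))
}

#' Standardised co-occurrence effect size
#'
#' Observed minus expected shared stations, scaled by the number of
#' stations: `(Q_obs - N1*N2/N) / N`, bounded in `[-1, 1]` and comparable
#' across studies.
#'
#' @inheritParams cooccurrence_test
#' @return effect size.
#' @export
cooccurrence_effect_size <- function(N, N1, N2, Q_obs) {
  (Q_obs - N1 * N2 / N) / N
}

#' Classify a species pair from its tail probabilities
#'
#' Negative association when `p_lt < alpha`, positive when `p_gt < alpha`,
#' random otherwise. Both tails significant is pathological (possible only
#' for tiny supports); the smaller tail wins and the result is flagged.
#'
#' @param p_lt,p_gt tail probabilities.
#' @param alpha significance level (default 0.05).
#' @return `"negative"`, `"positive"` or `"random"` (with attribute
#'   `flag = "both_tails"` in the pathological case).
#' @export
classify_cooccurrence <- function(p_lt, p_gt, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, p_lt >= 0, p_lt <= 1, p_gt >= 0, p_gt <= 1)
  if (p_lt < alpha && p_gt < alpha) {
    out <- if (p_lt <= p_gt) "negative" else "positive"
    attr(out, "flag") <- "both_tails"
    return(out)
  }
  if (p_lt < alpha) "negative" else if (p_gt < alpha) "positive" else "random"
}

#' Pairwise co-occurrence analysis of a detection matrix
#'
#' Runs the hypergeometric test for every unordered species pair over the
#' full station set (species absent from a station still contribute to
#' `N`). Pairs where the rarer species occupies fewer than `min_occ`
#' stations are reported but flagged `low_power`.
#'
#' @param mat binary station x species matrix from
#'   [build_detection_matrix()].
#' @param alpha significance level.
#' @param exclude species columns to drop.
#' @param min_occ low-power flag threshold on `min(N1, N2)` (default 5).
#' @return list with `pairs` (long data.frame: N, N1, N2, Q_obs, expected,
#'   p_lt, p_gt, effect_size, classification, low_power) and
#'   `effect_matrix` (symmetric S x S effect sizes, zero diagonal).
#' @export
cooccurrence_pairs <- function(mat, alpha = 0.05, exclude = NULL,
                               min_occ = 5) {
  mat <- mat[, setdiff(colnames(mat), exclude), drop = FALSE]
  species <- colnames(mat)
  s <- length(species)
  if (s < 2) stop("need at least two species")
  N <- nrow(mat)
  occ <- colSums(mat)
  eff <- matrix(0, s, s, dimnames = list(species, species))
  rows <- list(); k <- 0L
  for (i in seq_len(s - 1)) {
    for (j in (i + 1):s) {
      k <- k + 1L
      N1 <- occ[i]; N2 <- occ[j]
      Q <- sum(mat[, i] * mat[, j])
      tails <- cooccurrence_test(N, N1, N2, Q)
      es <- cooccurrence_effect_size(N, N1, N2, Q)
      eff[i, j] <- eff[j, i] <- es
      rows[[k]] <- data.frame(
        species_a = species[i], species_b = species[j],
        N = N, N1 = unname(N1), N2 = unname(N2), Q_obs = Q,
        expected = unname(N1 * N2 / N),
        p_lt = tails$p_lt, p_gt = tails$p_gt, effect_size = es,
        classification = as.character(
          classify_cooccurrence(tails$p_lt, tails$p_gt, alpha)),
        low_power = min(N1, N2) < min_occ,
        stringsAsFactors = FALSE)
    }
  }
  list(pairs = do.call(rbind, rows), effect_matrix = eff, alpha = alpha)
}
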