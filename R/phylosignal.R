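#' Brownian-motion variance-covariance matrix of a phylogeny
#'
#' Entry (i, j) is the sum of branch lengths shared on the paths from the
#' root to tips i and j (i.e. root-to-MRCA distance); the diagonal holds
#' root-to-tip distances. This is the expected trait covariance under
#' Brownian motion and the weight matrix for Blomberg's K.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2L) stop("need at least 2 tips", call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths", call. = FALSE)
  }
  ape::vcv.phylo(tree)
}

#' Blomberg's K phylogenetic signal
#'
#' Computes Blomberg's K for a continuous tip trait: the ratio of the
#' observed mean squared error of the trait (about its phylogenetically
#' corrected, generalized-least-squares mean) to the
#' phylogenetically-weighted mean squared error, standardized by the
#' Brownian-motion expectation of that ratio,
#' `(tr(V) - n / sum(V^-1)) / (n - 1)`. K ranges from 0 (no signal) upward;
#' K = 1 is the Brownian expectation and K is invariant to shifting or
#' positively rescaling the trait.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @param trait Named numeric vector (names = tip labels), covering every
#'   tip. Must have positive variance.
#' @param nsim Number of tip-label randomizations for a permutation p-value;
#'   0 (default) skips the test.
#' @param seed Optional integer seed for the randomization.
#' @return A one-row tibble: `k_statistic`, `n_tips`, `randomization_p`
#'   (`NA` when `nsim = 0`; otherwise the fraction of permuted datasets,
#'   observed included, whose K is at least the observed K).
#' @export
blomberg_k <- function(tree, trait, nsim = 0, seed = NULL) {
  V <- phylo_vcv(tree)
  tips <- rownames(V)
  if (is.null(names(trait))) {
    stop("trait must be named by tip label", call. = FALSE)
  }
  missing_tips <- setdiff(tips, names(trait))
  if (length(missing_tips) > 0L) {
    stop("trait missing for tip(s): ",
         paste(head(missing_tips, 5), collapse = ", "), call. = FALSE)
  }
  x <- as.numeric(trait[tips])
  if (anyNA(x)) stop("trait contains missing values", call. = FALSE)
  if (var(x) == 0) {
    stop("trait is constant; phylogenetic signal is undefined",
         call. = FALSE)
  }
  k_obs <- k_statistic(V, x)
  p <- NA_real_
  if (nsim > 0) {
    if (!is.null(seed)) {
      old <- .Random.seed_safe()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
    }
    k_null <- replicate(nsim, k_statistic(V, sample(x)))
    p <- (sum(k_null >= k_obs) + 1) / (nsim + 1)
  }
  tibble(k_statistic = k_obs, n_tips = length(x), randomization_p = p)
}

# Core K computation on a precomputed vcv; kept separate so permutations
# reuse the decomposition-independent pieces cheaply.
k_statistic <- function(V, x) {
  n <- length(x)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch))^2 < 1e-10 * max(diag(V))) {
    stop("phylogenetic covariance matrix is singular or near-singular",
         call. = FALSE)
  }
  ones <- rep(1, n)
  Vi_x <- backsolve(ch, forwardsolve(t(ch), x))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), ones))
  a_hat <- sum(Vi_x) / sum(Vi_1)          # GLS phylogenetic mean
  d <- x - a_hat
  mse0 <- sum(d^2) / (n - 1)
  Vi_d <- backsolve(ch, forwardsolve(t(ch), d))
  mse <- sum(d * Vi_d) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(Vi_1)) / (n - 1)
  (mse0 / mse) / expected
}

#' Phylogenetic signal in per-genus hybrid and neophyte counts
#'
#' Maps genus tallies onto the tips of a genus-level phylogeny and computes
#' Blomberg's K for each requested count column. Tips absent from the tally
#' table score zero (a genus with no recorded hybrids or neophytes); tally
#' rows absent from the tree are dropped and reported.
#'
#' @param tallies Output of [tally_by_genus()] (or any tibble with a `genus`
#'   column and the trait columns).
#' @param tree Genus-level [ape::phylo] with tip labels matching `genus`.
#' @param traits Character vector of tally columns to score.
#' @param nsim,seed Passed to [blomberg_k()].
#' @return A tibble with one row per trait: `trait`, `k_statistic`,
#'   `n_tips`, `randomization_p`; `read_report` attribute counts tally rows
#'   not on the tree.
#' @export
phylo_signal_counts <- function(tallies, tree,
                                traits = c("n_hybrids", "n_neophytes"),
                                nsim = 0, seed = NULL) {
  stopifnot(all(c("genus", traits) %in% names(tallies)))
  on_tree <- tallies$genus %in% tree$tip.label
  dropped <- sum(!on_tree)
  tal <- tallies[on_tree, , drop = FALSE]
  out <- purrr::map_dfr(traits, function(tr) {
    x <- setNames(rep(0, ape::Ntip(tree)), tree$tip.label)
    x[tal$genus] <- tal[[tr]]
    dplyr::mutate(blomberg_k(tree, x, nsim = nsim, seed = seed),
                  trait = tr, .before = 1)
  })
  attr(out, "read_report") <- tibble(
    tally_rows = nrow(tallies), rows_on_tree = nrow(tal),
    dropped_not_on_tree = dropped
  )
  out
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
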