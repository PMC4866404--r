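# Phylogenetic signal of the mucus-response traits: Blomberg's K with a
# tip-randomization p-value on a supplied rooted tree.  Tree parsing and the
# Brownian covariance matrix come from ape; the statistic itself is computed
# from first principles.

#' Read a rooted tree with branch lengths from newick text
#'
#' @param source newick string or path to a newick file.
#' @return An `ape::phylo` tree, validated: unique non-empty tip labels,
#'   branch lengths present and non-negative.
#' @export
read_newick <- function(source) {
  tree <- if (file.exists(source)) ape::read.tree(source) else
    ape::read.tree(text = source)
  if (is.null(tree)) stop("malformed newick input")
  if (is.null(tree$tip.label) || any(tree$tip.label == ""))
    stop("all tips must be labeled")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths")
  tree
}

#' Write a tree as newick text
#'
#' @param tree an `ape::phylo` tree.
#' @param file optional path; when `NULL` the newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree) else
    ape::write.tree(tree, file = file)
}

# align a named trait vector to the tree's tips, with strict matching
align_traits <- function(tree, traits) {
  if (is.null(names(traits))) stop("traits must be named by tip label")
  if (anyNA(traits)) stop("traits contain missing values")
  if (!setequal(names(traits), tree$tip.label))
    stop("trait names must match the tree tips exactly")
  traits[tree$tip.label]
}

# Brownian covariance with an epsilon nudge on zero-length terminal
# branches so V stays invertible
phylo_vcv <- function(tree, tip_epsilon = 1e-8) {
  nt <- length(tree$tip.label)
  term <- tree$edge[, 2] <= nt
  if (any(term & tree$edge.length == 0)) {
    height <- max(ape::node.depth.edgelength(tree))
    tree$edge.length[term & tree$edge.length == 0] <- tip_epsilon * height
    message("zero-length terminal branches nudged by ",
            format(tip_epsilon), " x tree height")
  }
  ape::vcv(tree)
}

#' Blomberg's K: phylogenetic signal of a continuous trait
#'
#' `K = (MSE0 / MSE) / E[MSE0 / MSE]`, where `MSE0` is the trait mean square
#' around the phylogenetically weighted mean `a = (1'V^-1 1)^-1 1'V^-1 x`,
#' `MSE = (x - a)' V^-1 (x - a) / (n - 1)` is the mean square in the
#' Brownian metric, and the Brownian expectation of their ratio is
#' `[tr(V) - n / (1'V^-1 1)] / (n - 1)`.  `K = 1` is the Brownian-motion
#' expectation; `K < 1` means closely related species resemble each other
#' less than Brownian evolution predicts, `K > 1` more.
#'
#' @param tree rooted `ape::phylo` tree with branch lengths.
#' @param traits named numeric vector, one value per tip.
#' @param tip_epsilon relative nudge applied to zero-length terminal
#'   branches to keep the Brownian covariance invertible.
#' @return Numeric K (> 0).
#' @examples
#' star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
#' blomberg_k(star, c(A = 1, B = 3, C = 0, D = 2))  # exactly 1
#' @export
blomberg_k <- function(tree, traits, tip_epsilon = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  x <- align_traits(tree, traits)
  n <- length(x)
  if (n < 3) stop("need at least 3 tips")
  if (stats::var(x) == 0) stop("constant trait vector: K undefined")
  V <- phylo_vcv(tree, tip_epsilon)
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular Brownian covariance matrix"))
  one <- rep(1, n)
  a <- sum(Vi %*% x) / sum(Vi)
  r <- x - a
  mse0 <- sum(r^2) / (n - 1)
  mse <- drop(t(r) %*% Vi %*% r) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  (mse0 / mse) / expected
}

#' Randomization p-value for Blomberg's K
#'
#' Destroys the phylogenetic signal by permuting trait values across tips
#' and reports the proportion of arrangements (the observed one included)
#' whose K is at least the observed K.
#'
#' @inheritParams blomberg_k
#' @param n_rand number of random tip permutations (the study used 1000).
#' @param seed optional integer seed.
#' @return List with `K`, `p.value`, `n_rand`.
#' @export
k_randomization_p <- function(tree, traits, n_rand = 1000, seed = NULL,
                              tip_epsilon = 1e-8) {
  if (n_rand < 1) stop("n_rand must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  x <- align_traits(tree, traits)
  k_obs <- blomberg_k(tree, x, tip_epsilon)
  k_rand <- vapply(seq_len(n_rand), function(i) {
    xs <- stats::setNames(sample(unname(x)), names(x))
    blomberg_k(tree, xs, tip_epsilon)
  }, numeric(1))
  list(K = k_obs,
       p.value = (1 + sum(k_rand >= k_obs)) / (n_rand + 1),
       n_rand = n_rand)
}

#' Synthetic stand-in tree for the nine study species
#'
#' A small rooted tree with branch lengths over the nine species of the
#' synthetic study, shipped for examples and end-to-end runs.  It is a
#' synthetic construction (topology loosely follows helicoid systematics:
#' the two \emph{Helix} species are sisters, the bradybaenid
#' \emph{F. fruticum} is the outermost tip), not an inferred phylogeny.
#'
#' @return An `ape::phylo` tree with 9 tips.
#' @export
synthetic_study_tree <- function() {
  read_newick(system.file("extdata", "synthetic_study_tree.nwk",
                          package = "dartpulse", mustWork = TRUE))
}

#' Per-species trait means for the phylogenetic-signal tests
#'
#' Collapses a per-trial table to species means of one column, returning the
#' named vector [blomberg_k()] expects.
#'
#' @param data per-trial data frame.
#' @param value_col column to average.
#' @param species_col species column.
#' @return Named numeric vector of species means.
#' @export
species_trait_means <- function(data, value_col, species_col = "species") {
  stopifnot(all(c(value_col, species_col) %in% names(data)))
  m <- tapply(data[[value_col]], data[[species_col]], mean)
  stats::setNames(as.numeric(m), names(m))
}
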