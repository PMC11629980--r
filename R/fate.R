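# Retention-fate classification of whole-genome-duplication ohnolog pairs
# from relative expression profiles, against an ancestral singleton proxy,
# with a singleton-pair divergence baseline.
#
# For a duplicate pair (D1, D2) with ancestral proxy A, the Euclidean
# distances E(D1,A), E(D2,A) and E(D1+D2,A) between relative expression
# profiles are compared against a cutoff derived from singleton pairs in
# sister species: cutoff = median(E(S1,S2)) + semi-interquartile range.
# The four rules (conserved / neofunctionalized / subfunctionalized /
# specialized) partition all outcomes.

#' Convert absolute expression to a relative profile
#'
#' Each entry is divided by the vector sum, giving the proportion of the
#' gene's total expression contributed by each tissue.
#'
#' @param x Non-negative numeric vector (TPM per tissue); at least one
#'   entry must be positive.
#' @return Numeric vector summing to 1.
#' @export
to_relative <- function(x) {
  if (any(x < 0)) stop("negative expression value")
  s <- sum(x)
  if (s == 0) stop("all-zero expression vector: gene not expressed in any tissue")
  x / s
}

#' Combined relative profile of a duplicate pair
#'
#' Element-wise sum of the two absolute vectors, then converted to a
#' relative profile.
#'
#' @param d1_abs,d2_abs Absolute expression vectors.
#' @return Relative profile of the combined expression.
#' @export
combined_profile <- function(d1_abs, d2_abs) to_relative(d1_abs + d2_abs)

#' Euclidean distance between two expression profiles
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative distance.
#' @export
profile_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length")
  sqrt(sum((a - b)^2))
}

#' Euclidean distances between paired singleton profiles
#'
#' @param s1,s2 Matrices of absolute expression (pairs x tissues), row i of
#'   `s1` paired with row i of `s2`.
#' @return Numeric vector of distances between relative profiles.
#' @export
singleton_distances <- function(s1, s2) {
  if (!all(dim(s1) == dim(s2))) stop("singleton matrices differ in shape")
  vapply(seq_len(nrow(s1)), function(i)
    profile_distance(to_relative(s1[i, ]), to_relative(s2[i, ])), numeric(1))
}

#' Divergence cutoff from singleton-pair distances
#'
#' cutoff = median + (Q3 - Q1)/2 (the semi-interquartile range), with
#' linear-interpolation quartiles by default; `hinges = TRUE` uses Tukey's
#' hinges (quantile type 2) instead.
#'
#' @param distances Numeric vector of singleton-pair distances (>= 4).
#' @param hinges Use Tukey hinges for the quartiles.
#' @return List with `distances`, `median`, `siqr`, `cutoff`.
#' @export
baseline_cutoff <- function(distances, hinges = FALSE) {
  if (length(distances) < 4)
    stop("need at least 4 singleton pairs for stable quartiles")
  q <- stats::quantile(distances, c(0.25, 0.5, 0.75), names = FALSE,
                       type = if (hinges) 2 else 7)
  siqr <- (q[3] - q[1]) / 2
  list(distances = distances, median = q[2], siqr = siqr,
       cutoff = q[2] + siqr)
}

#' Classify the retention fate of duplicate pairs
#'
#' Vectorized rule table (boundaries inclusive at the cutoff):
#' * conserved: E(D1,A) <= cutoff and E(D2,A) <= cutoff
#' * neofunctionalized_D1: E(D1,A) > cutoff, E(D2,A) <= cutoff
#' * neofunctionalized_D2: E(D1,A) <= cutoff, E(D2,A) > cutoff
#' * subfunctionalized: both > cutoff, E(D1+D2,A) <= cutoff
#' * specialized: all three > cutoff
#'
#' @param e_d1a,e_d2a,e_comb Distances to the ancestral profile.
#' @param cutoff Divergence cutoff (from [baseline_cutoff()]).
#' @return Character vector of fate labels.
#' @export
classify_fate <- function(e_d1a, e_d2a, e_comb, cutoff) {
  d1 <- e_d1a > cutoff; d2 <- e_d2a > cutoff; dc <- e_comb > cutoff
  ifelse(!d1 & !d2, "conserved",
  ifelse(d1 & !d2, "neofunctionalized_D1",
  ifelse(!d1 & d2, "neofunctionalized_D2",
  ifelse(!dc, "subfunctionalized", "specialized"))))
}

#' Distances and fate labels for a table of ohnolog triplets
#'
#' @param d1_abs,d2_abs,anc_abs Absolute expression matrices
#'   (triplets x tissues), rows aligned across the three.
#' @param cutoff Divergence cutoff.
#' @param ids Optional triplet identifiers.
#' @return data.frame with e_d1a, e_d2a, e_comb and fate per triplet.
#' @export
classify_triplets <- function(d1_abs, d2_abs, anc_abs, cutoff, ids = NULL) {
  stopifnot(all(dim(d1_abs) == dim(d2_abs)),
            all(dim(d1_abs) == dim(anc_abs)))
  n <- nrow(d1_abs)
  e1 <- numeric(n); e2 <- numeric(n); ec <- numeric(n)
  for (i in seq_len(n)) {
    a <- to_relative(anc_abs[i, ])
    e1[i] <- profile_distance(to_relative(d1_abs[i, ]), a)
    e2[i] <- profile_distance(to_relative(d2_abs[i, ]), a)
    ec[i] <- profile_distance(combined_profile(d1_abs[i, ], d2_abs[i, ]), a)
  }
  data.frame(triplet_id = if (is.null(ids)) seq_len(n) else ids,
             e_d1a = e1, e_d2a = e2, e_comb = ec,
             fate = classify_fate(e1, e2, ec, cutoff),
             stringsAsFactors = FALSE)
}

#' Fate proportions with pooled neofunctionalization
#'
#' @param fates Character vector of fate labels (directional neo labels are
#'   pooled into "neofunctionalized" for reporting).
#' @return data.frame fate, n, proportion over the four headline classes.
#' @export
fate_proportions <- function(fates) {
  if (!length(fates)) stop("no triplets")
  pooled <- ifelse(startsWith(fates, "neofunctionalized"),
                   "neofunctionalized", fates)
  lv <- c("conserved", "neofunctionalized", "subfunctionalized", "specialized")
  n <- table(factor(pooled, levels = lv))
  data.frame(fate = lv, n = as.integer(n),
             proportion = as.numeric(n) / length(fates),
             stringsAsFactors = FALSE)
}
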