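#' Herbivore richness of one plant
#'
#' Number of herbivore species recorded (count >= 1) on the plant.
#'
#' @param it an [interaction_table()].
#' @param plant plant species label.
#' @return integer richness.
#' @export
richness <- function(it, plant) {
  i <- match(plant, it$plants$species)
  if (is.na(i)) stop("unknown plant: ", plant, call. = FALSE)
  r <- sum(it$counts[i, ] >= 1)
  if (r == 0L) stop("plant '", plant, "' has no herbivores; ",
                    "apply drop_unusable_plants() first", call. = FALSE)
  r
}

#' Shared/exclusive herbivore counts for a plant pair
#'
#' From presence/absence: `a` herbivore species on both plants, `b` only on
#' `p1`, `c` only on `p2`.
#'
#' @param it an [interaction_table()].
#' @param p1,p2 distinct plant labels.
#' @return list with integers `a`, `b`, `c`.
#' @export
pairwise_abc <- function(it, p1, p2) {
  if (identical(p1, p2)) stop("p1 and p2 must differ", call. = FALSE)
  i <- match(p1, it$plants$species)
  j <- match(p2, it$plants$species)
  if (is.na(i)) stop("unknown plant: ", p1, call. = FALSE)
  if (is.na(j)) stop("unknown plant: ", p2, call. = FALSE)
  x <- it$counts[i, ] >= 1
  y <- it$counts[j, ] >= 1
  list(a = sum(x & y), b = sum(x & !y), c = sum(!x & y))
}

#' Jaccard dissimilarity from shared/exclusive counts
#'
#' `(b + c) / (a + b + c)`: sensitive to both richness difference and
#' species replacement.
#'
#' @param pc list with `a`, `b`, `c` as from [pairwise_abc()].
#' @return value in `[0, 1]`.
#' @export
jaccard_dissimilarity <- function(pc) {
  denom <- pc$a + pc$b + pc$c
  if (denom < 1) stop("Jaccard undefined: a = b = c = 0", call. = FALSE)
  (pc$b + pc$c) / denom
}

#' Simpson dissimilarity from shared/exclusive counts
#'
#' `min(b, c) / (min(b, c) + a)`: unaffected by richness difference,
#' captures species replacement only.
#'
#' @inheritParams jaccard_dissimilarity
#' @return value in `[0, 1]`.
#' @export
simpson_dissimilarity <- function(pc) {
  mbc <- min(pc$b, pc$c)
  if (mbc + pc$a < 1) stop("Simpson undefined: a = min(b,c) = 0", call. = FALSE)
  mbc / (mbc + pc$a)
}

#' Mean compositional dissimilarity of a focal plant versus natives
#'
#' Arithmetic mean of the pairwise index between the focal plant and each
#' co-occurring native plant (the focal plant itself always excluded).
#' Pairs with an undefined index are skipped with the comparator count
#' reduced, never imputed.
#'
#' @param it an [interaction_table()].
#' @param focal focal plant label.
#' @param native_set character vector of native comparator labels.
#' @param index `"jaccard"` or `"simpson"`.
#' @return list: `value`, `n_comparators`, `n_skipped`.
#' @export
mean_dissimilarity <- function(it, focal, native_set,
                               index = c("jaccard", "simpson")) {
  index <- match.arg(index)
  fn <- if (index == "jaccard") jaccard_dissimilarity else simpson_dissimilarity
  comp <- setdiff(native_set, focal)
  if (length(comp) == 0L) {
    stop("no native comparators for '", focal, "'", call. = FALSE)
  }
  vals <- vapply(comp, function(p) {
    tryCatch(fn(pairwise_abc(it, focal, p)), error = function(e) NA_real_)
  }, numeric(1))
  ok <- !is.na(vals)
  if (!any(ok)) stop("all pairwise indices undefined for '", focal, "'",
                     call. = FALSE)
  list(value = mean(vals[ok]), n_comparators = sum(ok),
       n_skipped = sum(!ok))
}

# Kullback-Leibler divergence of an integer allocation n (sum A) against
# availability q, in nats: sum over n>0 of (n/A) * log((n/A)/q).
kl_alloc <- function(n, A, q) {
  p <- n / A
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

# Exact minimum KL over integer allocations of A units across length(q)
# cells: depth-first enumeration of compositions with a branch-and-bound
# cut (continuous proportional completion bounds the remainder from
# below). Feasible for A <= 12, cells <= 8.
dmin_exact <- function(A, q) {
  P <- length(q)
  suffq <- rev(cumsum(rev(q)))
  term1 <- function(k, qq) if (k > 0) (k / A) * log((k / A) / qq) else 0
  best <- kl_alloc(proportional_fill(A, q), A, q)
  recurse <- function(cell, left, acc) {
    if (cell == P) {
      val <- acc + term1(left, q[P])
      if (val < best) best <<- val
      return()
    }
    if (left > 0) {
      lb <- acc + (left / A) * log((left / A) / suffq[cell])
      if (lb >= best) return()
    }
    for (k in 0:left) {
      recurse(cell + 1L, left - k, acc + term1(k, q[cell]))
    }
  }
  recurse(1L, A, 0)
  best
}

# largest-remainder rounding of the proportional (continuous-optimum)
# allocation of A units to weights q
proportional_fill <- function(A, q) {
  ideal <- A * q
  n <- floor(ideal)
  rem <- A - sum(n)
  if (rem > 0) {
    ord <- order(ideal - n, decreasing = TRUE)
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1
  }
  n
}

# Heuristic minimum: proportional fill, then steepest single-unit moves to
# a fixed point. Each move only changes two cells, so candidate deltas are
# O(P) per step.
dmin_heuristic <- function(A, q) {
  term <- function(k) {
    p <- k / A
    out <- numeric(length(k))
    nz <- p > 0
    out[nz] <- p[nz] * log(p[nz] / q[nz])
    out
  }
  n <- proportional_fill(A, q)
  repeat {
    cur_terms <- term(n)
    dec <- term(pmax(n - 1, 0)) - cur_terms
    dec[n == 0] <- Inf
    inc <- term(n + 1) - cur_terms
    i1 <- which.min(dec)
    incx <- inc
    incx[i1] <- Inf
    j1 <- which.min(incx)
    v1 <- dec[i1] + incx[j1]
    j2 <- which.min(inc)
    decx <- dec
    decx[j2] <- Inf
    i2 <- which.min(decx)
    v2 <- decx[i2] + inc[j2]
    if (min(v1, v2) >= -1e-13) break
    if (v1 <= v2) {
      n[i1] <- n[i1] - 1
      n[j1] <- n[j1] + 1
    } else {
      n[i2] <- n[i2] - 1
      n[j2] <- n[j2] + 1
    }
  }
  kl_alloc(n, A, q)
}

#' Bluethgen d' specialization of one herbivore
#'
#' Standardized Kullback-Leibler specialization of a herbivore's realized
#' host use against host availability. With `p_j` the herbivore's
#' proportional use of plant `j` and `q_j` plant `j`'s share of all
#' interactions in the network, `d_raw = sum p_j ln(p_j / q_j)`,
#' `d_max = ln(m / A)` (`m` grand total, `A` the herbivore's total), and
#' `d_min` the smallest KL value achievable by any integer allocation of
#' the `A` interactions (exact enumeration when `A <= 12` and the network
#' has `<= 8` plants, a proportional-fill plus single-unit-swap heuristic
#' otherwise). `d' = (d_raw - d_min) / (d_max - d_min)`, defined as 0 for
#' degenerate networks where `d_max = d_min`.
#'
#' @param it an [interaction_table()].
#' @param herbivore herbivore species label.
#' @param exact_limit_A,exact_limit_plants switch to the heuristic `d_min`
#'   above these sizes.
#' @return one-row data.frame: `herbivore`, `d_raw`, `d_min`, `d_max`,
#'   `d_prime`, `degenerate`.
#' @export
dprime <- function(it, herbivore, exact_limit_A = 12L,
                   exact_limit_plants = 8L) {
  j <- match(herbivore, it$herbivores$species)
  if (is.na(j)) stop("unknown herbivore: ", herbivore, call. = FALSE)
  counts <- it$counts
  A <- sum(counts[, j])
  m <- sum(counts)
  if (A < 1) stop("herbivore '", herbivore, "' has no interactions", call. = FALSE)
  q <- rowSums(counts) / m
  d_raw <- kl_alloc(counts[, j], A, q)
  d_max <- log(m / A)
  d_min <- if (A <= exact_limit_A && nrow(counts) <= exact_limit_plants) {
    dmin_exact(A, q)
  } else {
    # the realized allocation is itself feasible, so d_min <= d_raw is
    # enforced even when the local search stalls; with d_raw <= d_max
    # (row totals bound q from below) this pins d' into [0, 1]
    min(dmin_heuristic(A, q), d_raw)
  }
  degenerate <- (d_max - d_min) <= 1e-12
  d_prime <- if (degenerate) 0 else (d_raw - d_min) / (d_max - d_min)
  data.frame(herbivore = herbivore, d_raw = d_raw, d_min = d_min,
             d_max = d_max, d_prime = min(max(d_prime, 0), 1),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Mean d' of the herbivores on one plant
#'
#' Unweighted mean of [dprime()] over all herbivores recorded on the
#' plant. d' values can be precomputed once per table and passed in.
#'
#' @param it an [interaction_table()].
#' @param plant plant label.
#' @param dprime_table optional data.frame of precomputed [dprime()] rows
#'   for every herbivore in the table.
#' @return numeric mean d' in `[0, 1]`.
#' @export
mean_dprime_per_plant <- function(it, plant, dprime_table = NULL) {
  i <- match(plant, it$plants$species)
  if (is.na(i)) stop("unknown plant: ", plant, call. = FALSE)
  herbs <- it$herbivores$species[it$counts[i, ] >= 1]
  if (length(herbs) == 0L) stop("plant '", plant, "' has no herbivores",
                                call. = FALSE)
  if (is.null(dprime_table)) {
    dprime_table <- do.call(rbind, lapply(herbs, function(h) dprime(it, h)))
  }
  vals <- dprime_table$d_prime[match(herbs, dprime_table$herbivore)]
  if (anyNA(vals)) stop("dprime_table missing herbivores", call. = FALSE)
  mean(vals)
}

#' Assemble the per-plant analysis table for one assemblage
#'
#' One row per plant: herbivore richness, mean Jaccard and Simpson
#' dissimilarity versus co-occurring natives, mean d' of its herbivores,
#' and phylogenetic isolation. Plants whose metrics are undefined (e.g. a
#' sole native with no comparator) get `NA` with a warning.
#'
#' @param a a filtered, eligible [assemblage()].
#' @param tt a [tax_tree()] containing all plants of `a` as tips.
#' @param exclude_self passed to [phylo_isolation()].
#' @param dist_matrix optional precomputed [patristic_matrix()].
#' @return data.frame with columns `assemblage_id`, `species`, `origin`,
#'   `richness`, `mean_jaccard`, `mean_simpson`, `mean_dprime`,
#'   `phylo_isolation`, `n_native_comparators`, `total_richness`.
#' @export
build_plant_metrics <- function(a, tt, exclude_self = TRUE,
                                dist_matrix = NULL) {
  it <- a$table
  plants <- it$plants$species
  natives <- it$plants$species[it$plants$origin == "native"]
  if (is.null(dist_matrix)) dist_matrix <- patristic_matrix(tt)
  dpt <- do.call(rbind, lapply(it$herbivores$species, function(h) dprime(it, h)))
  rows <- lapply(plants, function(p) {
    mj <- tryCatch(mean_dissimilarity(it, p, natives, "jaccard"),
                   error = function(e) NULL)
    ms <- tryCatch(mean_dissimilarity(it, p, natives, "simpson"),
                   error = function(e) NULL)
    pi_rec <- tryCatch(
      phylo_isolation(tt, a, p, exclude_self = exclude_self,
                      dist_matrix = dist_matrix),
      error = function(e) NULL)
    if (is.null(mj) || is.null(ms) || is.null(pi_rec)) {
      warning("undefined metrics for plant '", p, "' in assemblage ",
              a$assemblage_id, "; row flagged NA", call. = FALSE)
    }
    data.frame(
      assemblage_id = a$assemblage_id, species = p,
      origin = it$plants$origin[match(p, plants)],
      richness = richness(it, p),
      mean_jaccard = if (is.null(mj)) NA_real_ else mj$value,
      mean_simpson = if (is.null(ms)) NA_real_ else ms$value,
      mean_dprime = mean_dprime_per_plant(it, p, dpt),
      phylo_isolation = if (is.null(pi_rec)) NA_real_ else pi_rec$phylo_isolation,
      n_native_comparators = if (is.null(mj)) NA_integer_ else mj$n_comparators,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$total_richness <- ncol(it$counts)
  out
}
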