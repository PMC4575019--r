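# Shared fixtures: everything is built in code, no data files.

# assemblage from a counts matrix + origin/guild vectors, with default labels
make_assemblage <- function(counts, origins, guilds = NULL, id = "T1",
                            plant_names = NULL, herb_names = NULL,
                            genus = NULL, family = NULL) {
  counts <- as.matrix(counts)
  np <- nrow(counts)
  nh <- ncol(counts)
  if (is.null(plant_names)) plant_names <- paste0("P", seq_len(np))
  if (is.null(herb_names)) herb_names <- paste0("H", seq_len(nh))
  if (is.null(guilds)) guilds <- rep(c("endophage", "exophage"), length.out = nh)
  if (is.null(genus)) genus <- paste0("g", seq_len(np))
  if (is.null(family)) family <- paste0("f", seq_len(np))
  assemblage(id, interaction_table(
    counts,
    plants = data.frame(species = plant_names, genus = genus, family = family,
                        origin = origins, stringsAsFactors = FALSE),
    herbivores = data.frame(species = herb_names, guild = guilds,
                            stringsAsFactors = FALSE)))
}

# random interaction matrix with no zero row/column (retry under a seed-fixed
# stream; callers set the seed)
random_table <- function(np, nh, max_count = 3) {
  repeat {
    m <- matrix(rpois(np * nh, 0.8), np, nh)
    m[m > max_count] <- max_count
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# the three-tip spec tree ((A:1,B:1):1,C:2) with taxonomy
abc_tree <- function() {
  tax_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"),
           data.frame(species = c("A", "B", "C"),
                      genus = c("ga", "ga", "gc"),
                      family = c("fa", "fa", "fc"),
                      stringsAsFactors = FALSE))
}

# Independent brute-force d' oracle: enumerates every integer allocation of
# the herbivore's total via expand.grid (structurally unlike the package's
# recursive branch-and-bound), and applies the definition directly.
oracle_dprime <- function(counts, j) {
  counts <- as.matrix(counts)
  A <- sum(counts[, j])
  m <- sum(counts)
  q <- rowSums(counts) / m
  P <- nrow(counts)
  p <- counts[, j] / A
  d_raw <- sum(ifelse(p > 0, p * log(p / q), 0))
  d_max <- log(m / A)
  if (P == 1) {
    d_min <- 0
  } else {
    grid <- as.matrix(expand.grid(rep(list(0:A), P - 1)))
    last <- A - rowSums(grid)
    grid <- cbind(grid[last >= 0, , drop = FALSE], last[last >= 0])
    pm <- grid / A
    lg <- log(sweep(pm, 2, q, "/"))
    lg[pm == 0] <- 0
    d_min <- min(rowSums(pm * lg))
  }
  d_prime <- if (d_max - d_min <= 1e-12) 0 else (d_raw - d_min) / (d_max - d_min)
  list(d_raw = d_raw, d_min = d_min, d_max = d_max, d_prime = d_prime)
}

# root-to-tip depth spread, relative to height
ultrametric_spread <- function(tt) {
  d <- ape::node.depth.edgelength(tt$tree)[seq_along(tt$tree$tip.label)]
  (max(d) - min(d)) / max(d)
}

# small simulated world shared by slower tests
small_config <- function(seed = 11L, ...) {
  simulation_config(n_assemblages = 5L, plants_per_assemblage = 12L,
                    herbivores_range = c(5L, 25L), regional_pool_size = 60L,
                    seed = seed, ...)
}
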