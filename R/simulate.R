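#' Simulation configuration
#'
#' Parameters of the synthetic plant-herbivore world. Defaults emulate the
#' compiled-literature setting the pipeline is designed for: 30 local
#' assemblages, about two dozen usable plants each, local herbivore
#' richness between 5 and 90 species, a minority of exotic plants with at
#' least three per assemblage, and herbivore host use whose probability
#' decays exponentially with the patristic distance (in Myr) from the
#' herbivore's origin host. Endophages decay three times faster than
#' exophages, reflecting their narrower host ranges.
#'
#' @param n_assemblages number of local assemblages.
#' @param plants_per_assemblage plants sampled per assemblage (>= 5).
#' @param herbivores_range integer range (min, max) of herbivore species
#'   per assemblage.
#' @param exotic_fraction fraction of exotic plants (floored at 3 species).
#' @param regional_pool_size tips of the simulated regional phylogeny.
#' @param tree_model only `"yule"` is implemented.
#' @param birth_rate Yule speciation rate per Myr.
#' @param decay_lambda_endophage,decay_lambda_exophage attack-probability
#'   decay rates per Myr of patristic distance.
#' @param baseline_attack_prob attack probability at zero distance.
#' @param between_assemblage_sd SD of the per-assemblage log-scale random
#'   intercept.
#' @param guild_mix fraction of herbivores that are endophages.
#' @param clade_displacement weight (per unit of tree height) pulling
#'   exotic draws toward clades distant from the sampled natives; 0 makes
#'   origin and isolation orthogonal.
#' @param counts_mode `"binary"` (default) or `"counts"` (>= 1 truncated
#'   Poisson(3) per realized link, exercising the count pathway of d').
#' @param genus_age,family_age Myr cut depths assigning synthetic genera
#'   and families on the simulated tree.
#' @param seed integer RNG seed.
#' @return object of class `sim_config` (a named list).
#' @export
simulation_config <- function(n_assemblages = 30L,
                              plants_per_assemblage = 24L,
                              herbivores_range = c(5L, 90L),
                              exotic_fraction = 0.25,
                              regional_pool_size = 200L,
                              tree_model = "yule",
                              birth_rate = 0.1,
                              decay_lambda_endophage = 0.045,
                              decay_lambda_exophage = 0.015,
                              baseline_attack_prob = 0.4,
                              between_assemblage_sd = 0.5,
                              guild_mix = 0.5,
                              clade_displacement = 1,
                              counts_mode = c("binary", "counts"),
                              genus_age = 20,
                              family_age = 60,
                              seed = 1L) {
  counts_mode <- match.arg(counts_mode)
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$tree_model == "yule",
            cfg$birth_rate > 0,
            cfg$decay_lambda_endophage >= 0, cfg$decay_lambda_exophage >= 0,
            cfg$between_assemblage_sd >= 0,
            cfg$guild_mix >= 0, cfg$guild_mix <= 1,
            cfg$exotic_fraction >= 0, cfg$exotic_fraction <= 1)
  if (cfg$baseline_attack_prob <= 0 || cfg$baseline_attack_prob > 1) {
    stop("config error: baseline_attack_prob must be in (0, 1]", call. = FALSE)
  }
  if (cfg$plants_per_assemblage < 5L) {
    stop("config error: plants_per_assemblage must be >= 5 ",
         "(eligibility needs five plants)", call. = FALSE)
  }
  if (cfg$herbivores_range[1] < 5L ||
      cfg$herbivores_range[2] < cfg$herbivores_range[1]) {
    stop("config error: herbivores_range must be an increasing range ",
         "with minimum >= 5", call. = FALSE)
  }
  nx <- max(3L, round(cfg$exotic_fraction * cfg$plants_per_assemblage))
  if (cfg$plants_per_assemblage - nx < 1L) {
    stop("config error: exotic_fraction leaves no native plant at ",
         cfg$plants_per_assemblage, " plants (exotic floor is 3)",
         call. = FALSE)
  }
  if (cfg$regional_pool_size < 2L * cfg$plants_per_assemblage) {
    stop("config error: regional_pool_size should be at least twice ",
         "plants_per_assemblage", call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a dated Yule regional phylogeny with synthetic taxonomy
#'
#' Pure-birth ultrametric tree (branch lengths in Myr). Genera and
#' families are assigned by cutting the tree at fixed ages, so sister
#' clades share genera and grafting can be exercised realistically.
#'
#' @param n_tips number of species (>= 2).
#' @param birth_rate speciation rate per Myr.
#' @param seed RNG seed.
#' @param genus_age,family_age cut ages in Myr.
#' @return a [tax_tree()].
#' @export
simulate_tree <- function(n_tips, birth_rate = 0.1, seed = 1L,
                          genus_age = 20, family_age = 60) {
  stopifnot(n_tips >= 2)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  taxonomy <- data.frame(
    species = tree$tip.label,
    genus = paste0("g", cut_clusters(tree, genus_age)),
    family = paste0("f", cut_clusters(tree, family_age)),
    stringsAsFactors = FALSE)
  tax_tree(tree, taxonomy)
}

# Cluster id per tip: tips whose connecting path stays younger than `age`
# share a cluster (the oldest ancestor not older than `age`).
cut_clusters <- function(tree, age) {
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth[seq_len(ntip)]) - depth
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  anchor <- vapply(seq_len(ntip), function(tip) {
    node <- tip
    while (parent[node] != 0 && ages[parent[node]] <= age) node <- parent[node]
    node
  }, integer(1))
  match(anchor, unique(anchor))
}

#' Simulate one local plant-herbivore assemblage
#'
#' Native plants are drawn uniformly from the regional pool; exotics are
#' drawn with weights increasing in their mean distance to the sampled
#' natives (controlled by `clade_displacement`), so phylogenetic isolation
#' varies and can correlate with origin. Each herbivore gets a guild, an
#' origin host among the natives, and attacks plant `j` with probability
#' `baseline * exp(-lambda_guild * d(origin, j)) * exp(u)` (clipped to 1),
#' where `u` is the assemblage's log-scale random intercept. Zero-herbivore
#' plants and hostless herbivores are redrawn up to 50 times, then dropped.
#'
#' Consumes the current RNG stream; seed management belongs to the caller
#' (see [generate_dataset()]).
#'
#' @param tt regional [tax_tree()].
#' @param config a [simulation_config()].
#' @param index assemblage number (used in labels).
#' @param dist_matrix optional precomputed [patristic_matrix()].
#' @return list: `assemblage` and `ground_truth` (origin hosts, random
#'   intercept, decay rates, expected PI-effect sign).
#' @export
simulate_assemblage <- function(tt, config, index = 1L, dist_matrix = NULL) {
  dm <- if (is.null(dist_matrix)) patristic_matrix(tt) else dist_matrix
  pool <- tt$tree$tip.label
  h <- max(dm) / 2
  np <- config$plants_per_assemblage
  nx <- max(3L, as.integer(round(config$exotic_fraction * np)))
  nn <- np - nx

  natives <- sample(pool, nn)
  rest <- setdiff(pool, natives)
  wts <- exp(config$clade_displacement *
               rowMeans(dm[rest, natives, drop = FALSE]) / h)
  exotics <- sample(rest, nx, prob = wts)
  plants <- c(natives, exotics)
  origin <- c(rep("native", nn), rep("exotic", nx))

  nh <- sample(seq(config$herbivores_range[1], config$herbivores_range[2]), 1L)
  guild <- ifelse(runif(nh) < config$guild_mix, "endophage", "exophage")
  origin_host <- sample(natives, nh, replace = TRUE)
  lam <- ifelse(guild == "endophage", config$decay_lambda_endophage,
                config$decay_lambda_exophage)
  u <- rnorm(1L, 0, config$between_assemblage_sd)

  pmat <- vapply(seq_len(nh), function(j) {
    pmin(1, config$baseline_attack_prob *
           exp(-lam[j] * dm[plants, origin_host[j]]) * exp(u))
  }, numeric(np))
  draw <- function(p) as.numeric(runif(length(p)) < p)
  inter <- apply(pmat, 2, draw)
  dim(inter) <- dim(pmat)

  # retry-then-drop: hostless herbivores first, then empty plants
  for (pass in 1:3) {
    for (j in which(colSums(inter) == 0)) {
      for (try in 1:50) {
        inter[, j] <- draw(pmat[, j])
        if (any(inter[, j] > 0)) break
      }
    }
    keep_h <- colSums(inter) > 0
    for (i in which(rowSums(inter[, keep_h, drop = FALSE]) == 0)) {
      for (try in 1:50) {
        inter[i, keep_h] <- draw(pmat[i, keep_h])
        if (any(inter[i, keep_h] > 0)) break
      }
    }
    if (all(colSums(inter) > 0) && all(rowSums(inter) > 0)) break
  }
  keep_h <- colSums(inter) > 0
  inter <- inter[, keep_h, drop = FALSE]
  pmat_kept <- pmat[, keep_h, drop = FALSE]
  guild <- guild[keep_h]
  origin_host <- origin_host[keep_h]
  keep_p <- rowSums(inter) > 0
  inter <- inter[keep_p, , drop = FALSE]

  if (config$counts_mode == "counts") {
    on <- inter > 0
    # zero-truncated Poisson(3) counts per realized link
    inter[on] <- qpois(runif(sum(on), dpois(0, 3), 1), 3)
  }

  id <- sprintf("A%02d", index)
  herb_names <- sprintf("%s_h%03d", id, seq_along(guild))
  it <- interaction_table(
    inter,
    plants = data.frame(
      species = plants[keep_p],
      genus = tt$taxonomy$genus[match(plants[keep_p], tt$taxonomy$species)],
      family = tt$taxonomy$family[match(plants[keep_p], tt$taxonomy$species)],
      origin = origin[keep_p], stringsAsFactors = FALSE),
    herbivores = data.frame(species = herb_names, guild = guild,
                            stringsAsFactors = FALSE))
  a <- assemblage(id, it, metadata = list(index = index))
  truth <- list(assemblage_id = id, random_intercept = u,
                origin_hosts = setNames(origin_host, herb_names),
                lambda_endophage = config$decay_lambda_endophage,
                lambda_exophage = config$decay_lambda_exophage,
                expected_pi_sign_richness = "negative")
  list(assemblage = a, ground_truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Simulates the regional phylogeny, then the assemblages (regenerating
#' any assemblage that fails the eligibility screen, up to 20 attempts
#' each), and optionally writes the full file bundle: Newick tree,
#' taxonomy CSV, per-assemblage interaction edge lists and metadata CSVs,
#' a JSON manifest with the seed and config, and `ground_truth.json`.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory to write the bundle to.
#' @return list of class `sim_dataset`: `tree` (a `tax_tree`),
#'   `assemblages` (list), `ground_truth` (list), `config`, and
#'   `manifest`.
#' @export
generate_dataset <- function(config = simulation_config(), out_dir = NULL) {
  validate_sim_config(config)
  tt <- simulate_tree(config$regional_pool_size, config$birth_rate,
                      seed = config$seed, genus_age = config$genus_age,
                      family_age = config$family_age)
  dm <- patristic_matrix(tt)
  # analytic-ish feasibility: expected links per plant must clear the
  # eligibility floor by a margin
  dvals <- dm[upper.tri(dm)]
  lam_mix <- config$guild_mix * config$decay_lambda_endophage +
    (1 - config$guild_mix) * config$decay_lambda_exophage
  exp_links <- config$herbivores_range[1] * config$baseline_attack_prob *
    mean(exp(-lam_mix * dvals))
  if (exp_links < 0.05) {
    stop("config error: expected links per plant (", signif(exp_links, 2),
         ") too low for eligible assemblages; raise baseline_attack_prob ",
         "or lower decay rates", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  assemblages <- vector("list", config$n_assemblages)
  truths <- vector("list", config$n_assemblages)
  for (i in seq_len(config$n_assemblages)) {
    for (attempt in 1:20) {
      res <- simulate_assemblage(tt, config, index = i, dist_matrix = dm)
      a <- drop_unusable_plants(res$assemblage)
      if (check_eligibility(a)$passed) break
      a <- NULL
    }
    if (is.null(a)) {
      stop("config error: could not generate an eligible assemblage ",
           "in 20 attempts (assemblage ", i, ")", call. = FALSE)
    }
    assemblages[[i]] <- a
    truths[[i]] <- res$ground_truth
  }
  manifest <- list(
    seed = config$seed,
    n_assemblages = config$n_assemblages,
    config = unclass(config),
    config_hash = config_hash(config),
    assemblage_ids = vapply(assemblages, function(a) a$assemblage_id, ""))
  ds <- structure(list(tree = tt, assemblages = assemblages,
                       ground_truth = truths, config = config,
                       manifest = manifest), class = "sim_dataset")
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

# small stable polynomial hash of the JSON-serialized config
config_hash <- function(config) {
  bytes <- utf8ToInt(as.character(
    jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a simulated dataset to disk in the package's exchange formats
#'
#' @param ds a `sim_dataset` from [generate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tax_tree(ds$tree, file.path(out_dir, "tree.nwk"),
                 file.path(out_dir, "taxonomy.csv"))
  entries <- lapply(ds$assemblages, function(a) {
    id <- a$assemblage_id
    files <- list(interactions = paste0(id, "_interactions.csv"),
                  plants = paste0(id, "_plants.csv"),
                  herbivores = paste0(id, "_herbivores.csv"))
    write_interactions(a$table, file.path(out_dir, files$interactions), "edges")
    write.csv(a$table$plants, file.path(out_dir, files$plants),
              row.names = FALSE, quote = FALSE)
    write.csv(a$table$herbivores, file.path(out_dir, files$herbivores),
              row.names = FALSE, quote = FALSE)
    c(list(assemblage_id = id), files)
  })
  manifest <- ds$manifest
  manifest$tree <- "tree.nwk"
  manifest$taxonomy <- "taxonomy.csv"
  manifest$assemblages <- entries
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(ds$ground_truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return a `sim_dataset`-shaped list (without `config` class checks);
#'   `ground_truth` is `NULL` when the file is absent.
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mpath)
  tt <- read_tax_tree(file.path(dir, manifest$tree),
                      file.path(dir, manifest$taxonomy))
  assemblages <- lapply(manifest$assemblages, function(e) {
    pm <- read.csv(file.path(dir, e$plants), stringsAsFactors = FALSE)
    hm <- read.csv(file.path(dir, e$herbivores), stringsAsFactors = FALSE)
    it <- read_interactions(file.path(dir, e$interactions), "edges",
                            plant_meta = pm, herbivore_meta = hm)
    assemblage(e$assemblage_id, it)
  })
  gt_path <- file.path(dir, "ground_truth.json")
  structure(list(tree = tt, assemblages = assemblages,
                 ground_truth = if (file.exists(gt_path))
                   jsonlite::read_json(gt_path) else NULL,
                 manifest = manifest),
            class = "sim_dataset")
}
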