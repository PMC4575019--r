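#' Construct a plant-herbivore interaction table
#'
#' The canonical container for one local assemblage's bipartite interaction
#' data: an integer count matrix (plants in rows, herbivores in columns)
#' together with plant metadata (genus, family, origin) and herbivore
#' metadata (feeding guild). Presence/absence computations throughout the
#' package use `count >= 1`.
#'
#' @param counts nonnegative integer matrix, plants x herbivores.
#' @param plants data.frame with columns `species`, `genus`, `family`,
#'   `origin` (one of `"native"`, `"exotic"`, `"unknown"`); one row per
#'   matrix row, in order.
#' @param herbivores data.frame with columns `species` and `guild` (one of
#'   `"endophage"`, `"exophage"`, or `NA`); one row per matrix column.
#' @return an object of class `interaction_table`.
#' @export
interaction_table <- function(counts, plants, herbivores) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  plants <- as.data.frame(plants, stringsAsFactors = FALSE)
  herbivores <- as.data.frame(herbivores, stringsAsFactors = FALSE)
  for (col in c("genus", "family", "origin")) {
    if (is.null(plants[[col]])) plants[[col]] <- NA_character_
  }
  if (is.null(herbivores$guild)) herbivores$guild <- NA_character_
  it <- structure(
    list(counts = counts, plants = plants, herbivores = herbivores),
    class = "interaction_table"
  )
  validate_interaction_table(it)
}

validate_interaction_table <- function(it) {
  counts <- it$counts
  plants <- it$plants
  herbivores <- it$herbivores
  if (is.null(plants$species) || is.null(herbivores$species)) {
    stop("plant and herbivore metadata need a 'species' column", call. = FALSE)
  }
  plants$species <- as.character(plants$species)
  herbivores$species <- as.character(herbivores$species)
  if (nrow(counts) != nrow(plants) || ncol(counts) != nrow(herbivores)) {
    stop("count matrix dimensions do not match plant/herbivore lists",
         call. = FALSE)
  }
  if (any(!nzchar(plants$species)) || anyNA(plants$species)) {
    stop("empty plant species label", call. = FALSE)
  }
  if (anyDuplicated(plants$species)) {
    stop("duplicated plant labels: ",
         paste(unique(plants$species[duplicated(plants$species)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(herbivores$species)) {
    stop("duplicated herbivore labels: ",
         paste(unique(herbivores$species[duplicated(herbivores$species)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("interaction counts must be nonnegative", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("interaction counts must be integers", call. = FALSE)
  }
  bad <- !plants$origin %in% c("native", "exotic", "unknown") & !is.na(plants$origin)
  if (any(bad)) {
    stop("invalid plant origin: ", paste(unique(plants$origin[bad]), collapse = ", "),
         call. = FALSE)
  }
  badg <- !herbivores$guild %in% c("endophage", "exophage") & !is.na(herbivores$guild)
  if (any(badg)) {
    stop("invalid herbivore guild: ",
         paste(unique(herbivores$guild[badg]), collapse = ", "), call. = FALSE)
  }
  dimnames(counts) <- list(plants$species, herbivores$species)
  it$counts <- counts
  it$plants <- plants
  it$herbivores <- herbivores
  it
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("<interaction_table> ", nrow(x$counts), " plants x ", ncol(x$counts),
      " herbivores, ", sum(x$counts >= 1), " links\n", sep = "")
  invisible(x)
}

#' Read an interaction table from CSV
#'
#' Two dialects are supported. `"edges"`: columns `plant,herbivore,count`
#' (header required; `count` optional, default 1; repeated rows sum their
#' counts). `"matrix"`: first column holds plant labels, remaining column
#' names are herbivore labels, cells are counts.
#'
#' Plant and herbivore metadata (origin, guild, taxonomy) are attached from
#' optional metadata data.frames; species absent from the metadata get `NA`.
#'
#' @param path CSV file path.
#' @param dialect `"edges"` or `"matrix"`.
#' @param plant_meta optional data.frame `species,genus,family,origin`.
#' @param herbivore_meta optional data.frame `species,guild`.
#' @return an `interaction_table`.
#' @export
read_interactions <- function(path, dialect = c("edges", "matrix"),
                              plant_meta = NULL, herbivore_meta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "edges") {
    need <- c("plant", "herbivore")
    if (!all(need %in% names(raw))) {
      stop("edge list must have columns 'plant' and 'herbivore': ", path,
           call. = FALSE)
    }
    if (is.null(raw$count)) raw$count <- 1
    bad <- which(is.na(raw$plant) | is.na(raw$herbivore) | !nzchar(raw$plant) |
                   !nzchar(raw$herbivore) | is.na(suppressWarnings(as.numeric(raw$count))))
    if (length(bad)) {
      stop("malformed edge-list row at line ", bad[1] + 1L, " of ", path,
           call. = FALSE)
    }
    raw$count <- as.numeric(raw$count)
    if (any(raw$count < 0)) {
      stop("negative count at line ",
           which(raw$count < 0)[1] + 1L, " of ", path, call. = FALSE)
    }
    plants <- unique(as.character(raw$plant))
    herbs <- unique(as.character(raw$herbivore))
    counts <- matrix(0, length(plants), length(herbs),
                     dimnames = list(plants, herbs))
    for (i in seq_len(nrow(raw))) {
      counts[raw$plant[i], raw$herbivore[i]] <-
        counts[raw$plant[i], raw$herbivore[i]] + raw$count[i]
    }
  } else {
    if (ncol(raw) < 2) stop("matrix dialect needs >= 2 columns: ", path, call. = FALSE)
    plants <- as.character(raw[[1]])
    counts <- as.matrix(raw[, -1, drop = FALSE])
    storage.mode(counts) <- "double"
    if (anyNA(counts)) stop("non-numeric or missing cell in ", path, call. = FALSE)
    if (any(counts < 0)) stop("negative count in matrix file ", path, call. = FALSE)
    dimnames(counts) <- list(plants, colnames(raw)[-1])
    herbs <- colnames(counts)
  }
  interaction_table(counts,
                    plants = join_meta(plants, plant_meta,
                                       c("genus", "family", "origin")),
                    herbivores = join_meta(herbs, herbivore_meta, "guild"))
}

join_meta <- function(species, meta, cols) {
  out <- data.frame(species = species, stringsAsFactors = FALSE)
  for (col in cols) {
    out[[col]] <- if (!is.null(meta) && !is.null(meta[[col]])) {
      as.character(meta[[col]])[match(species, as.character(meta$species))]
    } else NA_character_
  }
  out
}

#' Write an interaction table to CSV
#'
#' @param it an `interaction_table`.
#' @param path output file.
#' @param dialect `"edges"` (only nonzero cells written) or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(it, path, dialect = c("edges", "matrix")) {
  dialect <- match.arg(dialect)
  if (dialect == "edges") {
    idx <- which(it$counts >= 1, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    df <- data.frame(plant = rownames(it$counts)[idx[, 1]],
                     herbivore = colnames(it$counts)[idx[, 2]],
                     count = it$counts[idx])
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(plant = rownames(it$counts), it$counts,
                     check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
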