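#' Construct a local plant-herbivore assemblage
#'
#' An assemblage is one local community: an interaction table plus an
#' identifier and free-form metadata (latitude, altitude, source, ...).
#'
#' @param assemblage_id unique string id.
#' @param table an [interaction_table()].
#' @param metadata named list of free-form metadata.
#' @return object of class `assemblage`.
#' @export
assemblage <- function(assemblage_id, table, metadata = list()) {
  stopifnot(is.character(assemblage_id), length(assemblage_id) == 1L,
            nzchar(assemblage_id), inherits(table, "interaction_table"))
  structure(list(assemblage_id = assemblage_id, table = table,
                 metadata = metadata),
            class = "assemblage")
}

#' @export
print.assemblage <- function(x, ...) {
  cat("<assemblage '", x$assemblage_id, "'> ", sep = "")
  print(x$table)
  invisible(x)
}

n_plants <- function(a) nrow(a$table$counts)
n_herbivores <- function(a) ncol(a$table$counts)

#' Drop unusable plants (and orphaned herbivores) from an assemblage
#'
#' Removes plants whose origin is `unknown` (or missing) and plants with no
#' recorded herbivore at all (all-zero rows): only plants consumed by at
#' least one herbivore enter the analysis. Herbivores left without any host
#' after plant removal are removed in cascade. Every removal is logged with
#' its reason.
#'
#' @param a an [assemblage()].
#' @return the filtered assemblage, with a data.frame attribute
#'   `"removal_log"` (columns `label`, `kind`, `reason`).
#' @export
drop_unusable_plants <- function(a) {
  it <- a$table
  log <- data.frame(label = character(), kind = character(),
                    reason = character(), stringsAsFactors = FALSE)
  unknown <- is.na(it$plants$origin) | it$plants$origin == "unknown"
  zero <- rowSums(it$counts >= 1) == 0
  drop <- unknown | zero
  if (any(drop)) {
    log <- rbind(log, data.frame(
      label = it$plants$species[drop], kind = "plant",
      reason = ifelse(unknown[drop], "unknown_origin", "zero_herbivores"),
      stringsAsFactors = FALSE))
    it$counts <- it$counts[!drop, , drop = FALSE]
    it$plants <- it$plants[!drop, , drop = FALSE]
  }
  orphan <- colSums(it$counts >= 1) == 0
  if (any(orphan)) {
    log <- rbind(log, data.frame(
      label = it$herbivores$species[orphan], kind = "herbivore",
      reason = "no_remaining_host", stringsAsFactors = FALSE))
    it$counts <- it$counts[, !orphan, drop = FALSE]
    it$herbivores <- it$herbivores[!orphan, , drop = FALSE]
  }
  out <- assemblage(a$assemblage_id,
                    interaction_table(it$counts, it$plants, it$herbivores),
                    a$metadata)
  attr(out, "removal_log") <- log
  if (nrow(it$counts) == 0L) attr(out, "empty") <- TRUE
  out
}

#' Check assemblage eligibility
#'
#' Applies the inclusion criteria used to screen local assemblages:
#' at least five plant species, at least five herbivore species, at least
#' ten species in total, at least three exotic plants, and the presence of
#' at least one native plant. Assumes [drop_unusable_plants()] has already
#' been applied.
#'
#' @param a an [assemblage()].
#' @return a one-row data.frame (class `eligibility_report`) with counts,
#'   a `passed` flag and a comma-separated `reasons` string of failed
#'   criterion codes (`min_plants`, `min_herbivores`, `min_total`,
#'   `min_exotics`, `min_natives`).
#' @export
check_eligibility <- function(a) {
  np <- n_plants(a)
  nh <- n_herbivores(a)
  nx <- sum(a$table$plants$origin == "exotic", na.rm = TRUE)
  nn <- sum(a$table$plants$origin == "native", na.rm = TRUE)
  reasons <- character()
  if (np < 5) reasons <- c(reasons, "min_plants")
  if (nh < 5) reasons <- c(reasons, "min_herbivores")
  if (np + nh < 10) reasons <- c(reasons, "min_total")
  if (nx < 3) reasons <- c(reasons, "min_exotics")
  if (nn < 1) reasons <- c(reasons, "min_natives")
  structure(data.frame(
    assemblage_id = a$assemblage_id, passed = length(reasons) == 0L,
    n_plants = np, n_herbivores = nh, n_exotic = nx, n_native = nn,
    reasons = paste(reasons, collapse = ","), stringsAsFactors = FALSE),
    class = c("eligibility_report", "data.frame"))
}

#' Split an assemblage by herbivore feeding guild
#'
#' Partitions the herbivores into an endophage-only and an exophage-only
#' sub-assemblage. Plants left with zero interactions in a sub-assemblage
#' are dropped from that sub-assemblage (via [drop_unusable_plants()]).
#' Eligibility of each sub-assemblage is re-checked and recorded, not
#' enforced: the `eligible_after_split` attribute flags sub-assemblages
#' that no longer satisfy the inclusion criteria.
#'
#' @param a an [assemblage()]; every herbivore must carry a guild label.
#' @return named list with elements `endophage` and `exophage`, each an
#'   assemblage (possibly empty, flagged with attribute `"empty"`).
#' @export
split_by_guild <- function(a) {
  g <- a$table$herbivores$guild
  if (anyNA(g)) {
    stop("missing guild label for herbivore(s): ",
         paste(head(a$table$herbivores$species[is.na(g)], 5), collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(c(endophage = "endophage", exophage = "exophage"), function(gl) {
    keep <- g == gl
    it <- interaction_table(a$table$counts[, keep, drop = FALSE],
                            a$table$plants,
                            a$table$herbivores[keep, , drop = FALSE])
    sub <- drop_unusable_plants(
      assemblage(paste0(a$assemblage_id, ".", gl), it, a$metadata))
    attr(sub, "eligible_after_split") <- check_eligibility(sub)$passed
    sub
  })
  out
}
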