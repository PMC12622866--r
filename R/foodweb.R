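# Species pool: three aphids, two parasitoid wasps, one hyperparasitoid wasp.
# Canonical addition order within each guild is fixed so that "+A"/"+P"
# comparisons between communities are well defined.
.species_pool <- data.frame(
  id            = c("Bb", "Le", "Mp", "Dr", "Ac", "Af"),
  display_name  = c("Brevicoryne brassicae", "Lipaphis erysimi",
                    "Myzus persicae", "Diaeretiella rapae",
                    "Aphidius colemani", "Alloxysta fuscicornis"),
  common_role   = c("aphid", "aphid", "aphid",
                    "parasitoid", "parasitoid", "hyperparasitoid"),
  trophic_level = c(1L, 1L, 1L, 2L, 2L, 3L),
  stringsAsFactors = FALSE
)

#' Species pool
#'
#' The six insect species from which all communities are assembled: aphids
#' *Brevicoryne brassicae* (the focal species, weakest competitor),
#' *Lipaphis erysimi* and *Myzus persicae* (strongest competitor); parasitoid
#' wasps *Diaeretiella rapae* and *Aphidius colemani*; and the hyperparasitoid
#' wasp *Alloxysta fuscicornis*.
#'
#' @return A data frame with columns `id`, `display_name`, `common_role` and
#'   `trophic_level` (1 = aphid, 2 = parasitoid, 3 = hyperparasitoid).
#' @export
species_pool <- function() .species_pool

.aphid_order <- c("Bb", "Le", "Mp")
.parasitoid_order <- c("Dr", "Ac")
.hyper_order <- "Af"

#' Community labels
#'
#' The 15 community labels form the full grid of 1-3 aphid species, 0-2
#' parasitoid species and an optional hyperparasitoid (only when at least one
#' parasitoid is present): 9 webs without and 6 with a hyperparasitoid.
#'
#' @return Character vector of the 15 labels, ordered by increasing species
#'   count, then trophic levels.
#' @export
community_labels <- function() {
  labs <- character(0)
  meta <- NULL
  for (na in 1:3) for (np in 0:2) for (nh in 0:1) {
    if (nh == 1L && np == 0L) next
    lab <- paste0(na, "A")
    if (np > 0) lab <- paste0(lab, "-", np, "P")
    if (nh > 0) lab <- paste0(lab, "-1H")
    labs <- c(labs, lab)
    meta <- rbind(meta, c(na + np + nh, 1L + (np > 0) + (nh > 0), np, nh))
  }
  ord <- order(meta[, 1], meta[, 2], meta[, 3], meta[, 4])
  labs[ord]
}

.parse_label <- function(label) {
  m <- regmatches(label, regexec("^([1-3])A(?:-([1-2])P)?(?:-(1)H)?$", label))[[1]]
  if (length(m) == 0) return(NULL)
  c(n_aphids = as.integer(m[2]),
    n_parasitoids = if (m[3] == "") 0L else as.integer(m[3]),
    n_hyper = if (m[4] == "") 0L else 1L)
}

#' Build one community food web
#'
#' Assembles the food web for one catalogue label, e.g. `"2A-1P"`. Species are
#' added in a fixed order within guilds (aphids: B. brassicae, L. erysimi,
#' M. persicae; parasitoids: D. rapae, A. colemani), so the focal aphid
#' *B. brassicae* is always the first species.
#'
#' @param label Community label of the form `"<n>A[-<m>P[-1H]]"`.
#' @return An object of class `foodweb`: list with `label`, `species` (data
#'   frame in canonical order), and guild counts `n_aphids`, `n_parasitoids`,
#'   `n_hyper`.
#' @examples
#' build_community("2A-1P")
#' @export
build_community <- function(label) {
  counts <- .parse_label(label)
  if (is.null(counts) || !(label %in% community_labels()))
    stop("unknown community label '", label, "'; valid labels are: ",
         paste(community_labels(), collapse = ", "))
  ids <- c(.aphid_order[seq_len(counts["n_aphids"])],
           .parasitoid_order[seq_len(counts["n_parasitoids"])],
           if (counts["n_hyper"] > 0) .hyper_order)
  sp <- .species_pool[match(ids, .species_pool$id), , drop = FALSE]
  rownames(sp) <- NULL
  structure(list(label = label, species = sp,
                 n_aphids = unname(counts["n_aphids"]),
                 n_parasitoids = unname(counts["n_parasitoids"]),
                 n_hyper = unname(counts["n_hyper"])),
            class = "foodweb")
}

#' @export
print.foodweb <- function(x, ...) {
  cat("<foodweb>", x$label, ":", nrow(x$species), "species,",
      max(x$species$trophic_level), "trophic level(s)\n")
  cat("  ", paste(x$species$id, collapse = " -> "), "\n")
  invisible(x)
}

#' The full community catalogue
#'
#' @return List of the 15 `foodweb` objects in `community_labels()` order
#'   (increasing species count, then trophic levels; `"1A"` first).
#' @export
community_catalogue <- function() {
  lapply(community_labels(), build_community)
}

#' Export the catalogue as a data frame
#'
#' @return Data frame with one row per community: `label`, space-separated
#'   `species`, and guild counts.
#' @export
catalogue_table <- function() {
  webs <- community_catalogue()
  data.frame(
    label = vapply(webs, function(w) w$label, ""),
    species = vapply(webs, function(w) paste(w$species$id, collapse = " "), ""),
    n_aphids = vapply(webs, function(w) w$n_aphids, 0L),
    n_parasitoids = vapply(webs, function(w) w$n_parasitoids, 0L),
    n_hyper = vapply(webs, function(w) w$n_hyper, 0L),
    stringsAsFactors = FALSE
  )
}
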