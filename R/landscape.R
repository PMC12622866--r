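# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means: use the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.new_landscape <- function(n, edges, kind) {
  edges <- matrix(as.integer(edges), ncol = 2)
  # normalise: smaller id first, sorted, unique
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
  stopifnot(all(edges[, 1] != edges[, 2]), all(edges >= 0), all(edges < n))
  deg <- tabulate(c(edges[, 1], edges[, 2]) + 1L, nbins = n)
  structure(list(n_patches = as.integer(n), edges = edges,
                 degree = as.integer(deg), kind = kind),
            class = "patch_landscape")
}

#' Star landscape
#'
#' One hub patch (id 0) connected to `n_peripheral` leaf patches. The
#' experimental landscape is `star_landscape(4)`: five patches, hub degree 4.
#'
#' @param n_peripheral Number of leaves (>= 1).
#' @return A `patch_landscape`: `n_patches`, `edges` (two-column 0-based
#'   matrix), `degree`, `kind`.
#' @export
star_landscape <- function(n_peripheral) {
  if (n_peripheral < 1) stop("n_peripheral must be >= 1")
  .new_landscape(n_peripheral + 1L,
                 cbind(0L, seq_len(n_peripheral)), "star")
}

#' Scale-free landscape
#'
#' Preferential-attachment graph started from a triangle: each new patch
#' attaches to `attach` distinct existing patches chosen with probability
#' proportional to current degree. This yields a few highly connected hubs
#' and many low-degree peripheral patches, and is always connected. For the
#' triangle seed the edge count is `attach * (n - attach) + 1`.
#'
#' @param n Number of patches (>= attach + 1).
#' @param attach Edges added per new patch (default 2).
#' @param seed Optional integer seed; fixed seed reproduces the graph.
#' @return A `patch_landscape` of kind `"scale_free"`.
#' @export
scale_free_landscape <- function(n, attach = 2, seed = NULL) {
  if (n < attach + 1) stop("n must be >= attach + 1")
  with_seed(seed, {
    if (n == attach + 1) {
      # complete graph on attach+1 nodes (triangle when attach = 2)
      idx <- utils::combn(n, 2) - 1L
      return(.new_landscape(n, t(idx), "scale_free"))
    }
    seed_n <- 3L
    edges <- matrix(c(0L, 1L, 0L, 2L, 1L, 2L), ncol = 2, byrow = TRUE)
    deg <- rep(2L, seed_n)
    for (v in seq(seed_n, n - 1L)) {
      existing <- seq_len(v) - 1L
      targets <- sample(existing, size = attach, replace = FALSE, prob = deg)
      edges <- rbind(edges, cbind(v, targets))
      deg <- c(deg, attach)
      deg[targets + 1L] <- deg[targets + 1L] + 1L
    }
    .new_landscape(n, edges, "scale_free")
  })
}

#' @export
print.patch_landscape <- function(x, ...) {
  cat("<patch_landscape>", x$kind, ":", x$n_patches, "patches,",
      nrow(x$edges), "edges; degree range",
      min(x$degree), "-", max(x$degree), "\n")
  invisible(x)
}

# n x n symmetric 0/1 adjacency matrix
adjacency_matrix <- function(landscape) {
  n <- landscape$n_patches
  adj <- matrix(0, n, n)
  adj[landscape$edges + 1L] <- 1
  adj[landscape$edges[, 2:1, drop = FALSE] + 1L] <- 1
  adj
}

is_connected_landscape <- function(landscape) {
  n <- landscape$n_patches
  if (n == 1L) return(TRUE)
  adj <- adjacency_matrix(landscape)
  seen <- logical(n); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Select initially populated patches
#'
#' Chooses the patches that receive a community at the start of a run.
#' Central patches are those of highest degree (ties broken by smaller id,
#' deterministic); peripheral patches are those of lowest degree (ties broken
#' at random under `seed`, since e.g. all leaves of a star are equivalent).
#'
#' @param landscape A `patch_landscape`.
#' @param number Number of populated patches, 1 or 4 in the study design.
#' @param location `"central"` or `"peripheral"`.
#' @param seed Optional integer seed for peripheral tie-breaking.
#' @return A `placement`: list with `config_label` (e.g. `"4P"`), `populated`
#'   (0-based patch ids), `number_factor`, `location_factor`.
#' @export
select_placement <- function(landscape, number, location = c("central", "peripheral"),
                             seed = NULL) {
  location <- match.arg(location)
  n <- landscape$n_patches
  if (number > n) stop("landscape has fewer than ", number, " patches")
  deg <- landscape$degree
  ids <- seq_len(n) - 1L
  if (location == "central") {
    populated <- ids[order(-deg, ids)][seq_len(number)]
  } else {
    populated <- with_seed(seed, {
      # random tie-break: random rank within equal-degree groups
      ids[order(deg, sample.int(n))][seq_len(number)]
    })
  }
  structure(list(
    config_label = paste0(number, if (location == "central") "C" else "P"),
    populated = sort(as.integer(populated)),
    number_factor = as.integer(number),
    location_factor = location
  ), class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat("<placement>", x$config_label, ": patches {",
      paste(x$populated, collapse = ", "), "} populated\n")
  invisible(x)
}

#' Write/read a landscape as an edge-list CSV
#'
#' Format: a comment line `# n_patches=<n>`, then a `from,to` header and one
#' row per undirected edge (0-based ids).
#'
#' @param landscape A `patch_landscape`.
#' @param path File path.
#' @return `read_landscape` returns the `patch_landscape`.
#' @export
write_landscape <- function(landscape, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# n_patches=", landscape$n_patches), con)
  writeLines("from,to", con)
  writeLines(paste(landscape$edges[, 1], landscape$edges[, 2], sep = ","), con)
  invisible(path)
}

#' @rdname write_landscape
#' @param kind Landscape kind recorded on read (the file stores topology only).
#' @export
read_landscape <- function(path, kind = "custom") {
  first <- readLines(path, n = 1)
  n <- as.integer(sub("^# n_patches=", "", first))
  if (is.na(n)) stop("missing '# n_patches=' header in ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("from", "to") %in% names(df)))
    stop("edge list must have columns 'from' and 'to'")
  .new_landscape(n, cbind(df$from, df$to), kind)
}

#' Write a placement as CSV (patch_id, populated flag)
#' @param placement A `placement`.
#' @param landscape The landscape it refers to.
#' @param path File path.
#' @export
write_placement <- function(placement, landscape, path) {
  ids <- seq_len(landscape$n_patches) - 1L
  utils::write.csv(
    data.frame(patch_id = ids, populated = as.integer(ids %in% placement$populated)),
    path, row.names = FALSE)
  invisible(path)
}
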