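# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower) stopf("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower) stopf("`%s` must be >= %g", name, lower)
  if (strict_upper && x >= upper) stopf("`%s` must be < %g", name, upper)
  if (!strict_upper && x > upper) stopf("`%s` must be <= %g", name, upper)
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so simulations don't perturb user code.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Label 8-connected components of a logical matrix. EBImage::bwlabel is
# 4-connected, so we build the pixel adjacency graph and take its components.
label_components8 <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edges <- vector("list", 4L)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(shifts)) {
    r2 <- r + shifts[[k]][1L]
    c2 <- cc + shifts[[k]][2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- integer(sum(ok))
    j <- id[cbind(r2[ok], c2[ok])]
    keep <- j > 0L
    edges[[k]] <- cbind(id[idx][ok][keep], j[keep])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, as.vector(t(e)))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# Relabel a component image so labels run 1..K ordered by decreasing pixel
# count, ties broken by the lexicographically smallest (row, col) pixel.
relabel_by_size <- function(lab) {
  labs <- sort(unique(lab[lab > 0L]))
  if (!length(labs)) return(lab)
  info <- lapply(labs, function(l) {
    px <- which(lab == l, arr.ind = TRUE)
    o <- order(px[, 1L], px[, 2L])
    c(count = nrow(px), row = unname(px[o[1L], 1L]),
      col = unname(px[o[1L], 2L]))
  })
  info <- do.call(rbind, info)
  ord <- order(-info[, "count"], info[, "row"], info[, "col"])
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_along(ord)) out[lab == labs[ord[k]]] <- k
  out
}
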