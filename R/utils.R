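#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
#' @importFrom EBImage erode makeBrush bwlabel fillHull watershed distmap
NULL

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators never perturb user randomness.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

abort_validation <- function(msg) stop(msg, call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    abort_validation(sprintf("`%s` must be > 0", name))
  invisible(x)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged with a union-find over label ids.
label8 <- function(mask) {
  mask <- mask != 0
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow = nrow(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: (i,j)-(i+1,j+1) and (i+1,j)-(i,j+1)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  idx <- which(a > 0L & b > 0L & a != b)
  for (k in idx) union2(a[k], b[k])
  a <- lab[-1, -nc]; b <- lab[-nr, -1]
  idx <- which(a > 0L & b > 0L & a != b)
  for (k in idx) union2(a[k], b[k])
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab
}

# Per-label pixel linear indices, centroids (row, col) and areas.
component_stats <- function(lab) {
  pos <- which(lab > 0L)
  if (length(pos) == 0L)
    return(list(pixels = list(), centroid = matrix(numeric(0), 0, 2), area = integer(0)))
  ids <- lab[pos]
  nr <- nrow(lab)
  ord <- order(ids)
  pos <- pos[ord]; ids <- ids[ord]
  pixels <- split(pos, ids)
  rows <- (pos - 1L) %% nr + 1L
  cols <- (pos - 1L) %/% nr + 1L
  cy <- vapply(split(rows, ids), mean, numeric(1))
  cx <- vapply(split(cols, ids), mean, numeric(1))
  list(pixels = pixels,
       centroid = cbind(row = cy, col = cx),
       area = vapply(pixels, length, integer(1)))
}
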