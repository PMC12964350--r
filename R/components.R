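# Connected-component labelling on binary masks.
#
# Masks are matrices indexed [row, col] with image pixel (x, y) = (col-1,
# row-1): x grows rightwards, y downwards, origin at the top-left pixel
# centre. Components use 8-connectivity. Labelling is run-based (vertical
# runs per column joined with union-find), which is fast in plain R because
# arena frames contain a handful of compact blobs, not textured foreground.

as_binary_mask <- function(mask) {
  if (is.logical(mask)) {
    m <- mask
    m[is.na(m)] <- FALSE
    return(m)
  }
  if (is.numeric(mask)) {
    return(!is.na(mask) & mask != 0)
  }
  stop("`mask` must be a logical or numeric matrix.", call. = FALSE)
}

# Vertical foreground runs per column, labelled by 8-connected component.
# Returns NULL for an empty mask, else a list of parallel vectors:
# col, r0, r1 (1-based matrix indices, run spans rows r0..r1) and comp
# (component label 1..k), plus comp_sizes (pixel counts per label).
cc_runs <- function(mask) {
  mask <- as_binary_mask(mask)
  if (!any(mask)) return(NULL)
  nr <- nrow(mask)
  v <- as.vector(mask) # column-major: runs along columns
  d <- diff(c(FALSE, v, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  # discard runs spanning a column boundary by splitting at column edges
  col_of <- function(i) (i - 1L) %/% nr + 1L
  # a run crossing a column boundary is impossible only if we split it:
  cs <- col_of(starts); ce <- col_of(ends)
  if (any(cs != ce)) {
    # split wrap-around runs at column boundaries
    s2 <- integer(0); e2 <- integer(0)
    for (i in seq_along(starts)) {
      a <- starts[i]; b <- ends[i]
      while (col_of(a) != col_of(b)) {
        cut <- col_of(a) * nr
        s2 <- c(s2, a); e2 <- c(e2, cut)
        a <- cut + 1L
      }
      s2 <- c(s2, a); e2 <- c(e2, b)
    }
    starts <- s2; ends <- e2
  }
  run_col <- col_of(starts)
  r0 <- starts - (run_col - 1L) * nr
  r1 <- ends - (run_col - 1L) * nr
  n <- length(starts)

  # union-find over runs
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ucols <- unique(run_col)
  idx_by_col <- split(seq_len(n), run_col)
  for (ci in seq_along(ucols)[-1]) {
    c_prev <- ucols[ci - 1L]; c_cur <- ucols[ci]
    if (c_cur - c_prev != 1L) next
    ia <- idx_by_col[[as.character(c_prev)]]
    ib <- idx_by_col[[as.character(c_cur)]]
    for (a in ia) {
      for (b in ib) {
        # 8-connectivity: vertical overlap allowing one-row diagonal touch
        if (r0[a] <= r1[b] + 1L && r0[b] <= r1[a] + 1L) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- match(roots, unique(roots))
  lens <- r1 - r0 + 1L
  sizes <- vapply(seq_len(max(comp)), function(k) sum(lens[comp == k]), numeric(1))
  list(col = run_col, r0 = r0, r1 = r1, comp = comp, comp_sizes = sizes)
}

# Rebuild the logical mask of one labelled component.
runs_to_mask <- function(runs, k, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  sel <- which(runs$comp == k)
  for (i in sel) m[runs$r0[i]:runs$r1[i], runs$col[i]] <- TRUE
  m
}

# Per-component area (px) and centroid (pixel-mean, 0-based x/y) straight
# from the run encoding; used by the tracking backend where the polygon
# centroid is not needed.
component_stats <- function(runs) {
  k <- max(runs$comp)
  lens <- runs$r1 - runs$r0 + 1
  row_sums <- (runs$r0 + runs$r1) / 2 * lens
  area <- numeric(k); sx <- numeric(k); sy <- numeric(k)
  for (i in seq_along(runs$comp)) {
    g <- runs$comp[i]
    area[g] <- area[g] + lens[i]
    sx[g] <- sx[g] + (runs$col[i] - 1) * lens[i]
    sy[g] <- sy[g] + row_sums[i] - lens[i] # rows are 1-based; y = row-1
  }
  tibble::tibble(component = seq_len(k), area_px = area,
                 x_px = sx / area, y_px = sy / area)
}

# Which component (if any) contains pixel (x, y)? 0-based coords.
component_at <- function(runs, x, y) {
  col <- as.integer(round(x)) + 1L
  row <- as.integer(round(y)) + 1L
  hit <- which(runs$col == col & runs$r0 <= row & runs$r1 >= row)
  if (length(hit) == 0L) return(NA_integer_)
  runs$comp[hit[1]]
}
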