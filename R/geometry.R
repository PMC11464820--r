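# Planar geometry primitives (projected CRS, meter units).
#
# Geometries are plain lists:
#   line    : list(type = "line",    parts = list(<n x 2 matrix>, ...))
#   polygon : list(type = "polygon", parts = list(list(<ring matrix>, ...), ...))
# A polygon part is a list of closed rings (first row == last row); the first
# ring is the exterior, the rest are holes, interpreted with the even-odd rule.

close_ring <- function(m) {
  m <- as.matrix(m)
  dimnames(m) <- NULL
  if (nrow(m) < 3) um_stop("ring needs at least 3 vertices")
  if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

bare_matrix <- function(m) {
  m <- as.matrix(m)
  dimnames(m) <- NULL
  m
}

geom_line <- function(parts) {
  if (is.matrix(parts)) parts <- list(parts)
  list(type = "line", parts = lapply(parts, bare_matrix))
}

geom_polygon <- function(parts) {
  # accept a bare ring, a list of rings (one part), or a list of parts
  if (is.matrix(parts)) parts <- list(list(parts))
  if (length(parts) && is.matrix(parts[[1]])) parts <- list(parts)
  list(type = "polygon",
       parts = lapply(parts, function(p) lapply(p, close_ring)))
}

# axis-aligned rectangle polygon
geom_rect <- function(xmin, ymin, xmax, ymax) {
  geom_polygon(rbind(c(xmin, ymin), c(xmax, ymin),
                     c(xmax, ymax), c(xmin, ymax), c(xmin, ymin)))
}

ring_area_signed <- function(m) {
  m <- close_ring(m)
  x <- m[, 1]; y <- m[, 2]
  n <- nrow(m)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# Area of a polygon geometry. Parts are summed (exterior minus holes); parts
# produced by line buffering may overlap at joins, in which case this is an
# upper bound on covered area.
geom_area <- function(g) {
  if (g$type != "polygon") um_stop("geom_area needs a polygon")
  sum(vapply(g$parts, function(p) {
    a <- vapply(p, function(r) abs(ring_area_signed(r)), 0)
    if (length(a) > 1) a[1] - sum(a[-1]) else a[1]
  }, 0))
}

path_length <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) return(0)
  sum(sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}

geom_length <- function(g) {
  if (g$type != "line") um_stop("geom_length needs a line")
  sum(vapply(g$parts, path_length, 0))
}

geom_bbox <- function(g) {
  mats <- if (g$type == "line") g$parts else unlist(g$parts, recursive = FALSE)
  xs <- unlist(lapply(mats, function(m) m[, 1]))
  ys <- unlist(lapply(mats, function(m) m[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

geom_is_valid <- function(g) {
  ok <- function(m) nrow(m) >= 2 && all(is.finite(m))
  if (g$type == "line") {
    length(g$parts) > 0 && all(vapply(g$parts, ok, TRUE))
  } else {
    length(g$parts) > 0 && all(vapply(unlist(g$parts, recursive = FALSE),
      function(r) nrow(r) >= 4 && all(is.finite(r)) &&
        abs(ring_area_signed(r)) > 0, TRUE))
  }
}

# Even-odd point-in-rings test, vectorized over points.
points_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    ring <- close_ring(ring)
    n <- nrow(ring)
    x1 <- ring[-n, 1]; y1 <- ring[-n, 2]
    x2 <- ring[-1, 1]; y2 <- ring[-1, 2]
    for (e in seq_len(n - 1)) {
      if (y1[e] == y2[e]) next
      crosses <- ((y1[e] > py) != (y2[e] > py)) &
        (px < (x2[e] - x1[e]) * (py - y1[e]) / (y2[e] - y1[e]) + x1[e])
      inside <- xor(inside, crosses)
    }
  }
  inside
}

points_in_polygon <- function(px, py, g) {
  stopifnot(g$type == "polygon")
  inside <- rep(FALSE, length(px))
  for (part in g$parts) {
    inside <- inside | points_in_rings(px, py, part)
  }
  inside
}

# --- clipping ---------------------------------------------------------------

# Sutherland-Hodgman clip of one ring against an axis-aligned rectangle.
# Returns a closed ring matrix or NULL when nothing remains.
clip_ring_rect <- function(ring, bbox) {
  ring <- close_ring(ring)
  pts <- ring[-nrow(ring), , drop = FALSE]
  edges <- list(
    list(keep = function(p) p[, 1] >= bbox["xmin"], ax = 1, v = bbox[["xmin"]]),
    list(keep = function(p) p[, 1] <= bbox["xmax"], ax = 1, v = bbox[["xmax"]]),
    list(keep = function(p) p[, 2] >= bbox["ymin"], ax = 2, v = bbox[["ymin"]]),
    list(keep = function(p) p[, 2] <= bbox["ymax"], ax = 2, v = bbox[["ymax"]])
  )
  for (ed in edges) {
    if (nrow(pts) == 0) return(NULL)
    keep <- ed$keep(pts)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(pts)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a <- pts[i, ]; b <- pts[j, ]
      ain <- keep[i]; bin <- keep[j]
      cross_pt <- function() {
        t <- (ed$v - a[ed$ax]) / (b[ed$ax] - a[ed$ax])
        a + t * (b - a)
      }
      if (ain && bin) {
        out <- rbind(out, b)
      } else if (ain && !bin) {
        out <- rbind(out, cross_pt())
      } else if (!ain && bin) {
        out <- rbind(out, cross_pt(), b)
      }
    }
    pts <- out
  }
  if (nrow(pts) < 3) return(NULL)
  ring <- close_ring(bare_matrix(pts))
  if (abs(ring_area_signed(ring)) <= 0) return(NULL)
  ring
}

# Liang-Barsky clip of segment (p, q) to rectangle; NULL if outside.
clip_segment_rect <- function(p, q, bbox) {
  d <- q - p
  t0 <- 0; t1 <- 1
  pr <- c(-d[1], d[1], -d[2], d[2])
  qr <- c(p[1] - bbox[["xmin"]], bbox[["xmax"]] - p[1],
          p[2] - bbox[["ymin"]], bbox[["ymax"]] - p[2])
  for (k in 1:4) {
    if (pr[k] == 0) {
      if (qr[k] < 0) return(NULL)
    } else {
      r <- qr[k] / pr[k]
      if (pr[k] < 0) {
        if (r > t1) return(NULL)
        if (r > t0) t0 <- r
      } else {
        if (r < t0) return(NULL)
        if (r < t1) t1 <- r
      }
    }
  }
  if (t0 > t1) return(NULL)
  bare_matrix(rbind(p + t0 * d, p + t1 * d))
}

# Clip a polyline part to a rectangle; returns list of part matrices (the
# line may leave and re-enter the window).
clip_line_part_rect <- function(m, bbox) {
  m <- as.matrix(m)
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(m) - 1)) {
    seg <- clip_segment_rect(m[i, ], m[i + 1, ], bbox)
    if (is.null(seg) || all(seg[1, ] == seg[2, ])) {
      if (!is.null(cur)) { out[[length(out) + 1]] <- cur; cur <- NULL }
      next
    }
    if (!is.null(cur) && all(abs(cur[nrow(cur), ] - seg[1, ]) < 1e-9)) {
      cur <- rbind(cur, seg[2, ])
    } else {
      if (!is.null(cur)) out[[length(out) + 1]] <- cur
      cur <- seg
    }
  }
  if (!is.null(cur)) out[[length(out) + 1]] <- cur
  out
}

clip_geom_rect <- function(g, bbox) {
  if (g$type == "polygon") {
    parts <- list()
    for (part in g$parts) {
      rings <- Filter(Negate(is.null), lapply(part, clip_ring_rect, bbox = bbox))
      if (length(rings)) parts[[length(parts) + 1]] <- rings
    }
    if (!length(parts)) return(NULL)
    list(type = "polygon", parts = parts)
  } else {
    parts <- list()
    for (m in g$parts) parts <- c(parts, clip_line_part_rect(m, bbox))
    if (!length(parts)) return(NULL)
    list(type = "line", parts = parts)
  }
}

# --- buffering --------------------------------------------------------------

# Buffer a polyline to total width `width`: flat-capped rectangle per segment
# plus a regular-polygon disc at interior vertices (round joins). Returned as
# a multi-part polygon; parts may overlap at joins, which is safe because
# containment is "inside any part", not even-odd across parts.
buffer_path <- function(m, width, join_n = 16L) {
  m <- as.matrix(m)
  h <- width / 2
  parts <- list()
  for (i in seq_len(nrow(m) - 1)) {
    p <- m[i, ]; q <- m[i + 1, ]
    d <- q - p
    len <- sqrt(sum(d^2))
    if (len == 0) next
    nvec <- c(-d[2], d[1]) / len * h
    ring <- rbind(p + nvec, q + nvec, q - nvec, p - nvec, p + nvec)
    parts[[length(parts) + 1]] <- list(ring)
  }
  if (!length(parts)) return(NULL)
  if (nrow(m) > 2) {
    ang <- seq(0, 2 * pi, length.out = join_n + 1)[-(join_n + 1)]
    circ <- cbind(cos(ang), sin(ang)) * h
    for (i in 2:(nrow(m) - 1)) {
      ring <- close_ring(sweep(circ, 2, m[i, ], "+"))
      parts[[length(parts) + 1]] <- list(ring)
    }
  }
  list(type = "polygon", parts = parts)
}

buffer_line_geom <- function(g, width) {
  stopifnot(g$type == "line")
  parts <- list()
  for (m in g$parts) {
    b <- buffer_path(m, width)
    if (!is.null(b)) parts <- c(parts, b$parts)
  }
  if (!length(parts)) return(NULL)
  list(type = "polygon", parts = parts)
}
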