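#' Electrode montage
#'
#' Channel labels with 3D scalp positions (unit sphere convention, +y nose,
#' +z vertex) and a 2D projection used for topography and triangulation.
#'
#' @param labels unique channel labels.
#' @param positions n x 3 numeric matrix of finite coordinates.
#' @param projection optional n x 2 matrix; defaults to an azimuthal
#'   equidistant projection about the vertex.
#' @return Object of class `eeg_montage`.
#' @export
montage <- function(labels, positions, projection = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stopf("positions must be n x 3")
  if (!all(is.finite(positions))) stopf("montage positions must be finite")
  if (length(labels) != nrow(positions)) stopf("labels/positions length mismatch")
  if (anyDuplicated(labels)) stopf("montage labels must be unique")
  if (is.null(projection)) {
    r <- sqrt(rowSums(positions^2))
    theta <- acos(pmin(pmax(positions[, 3] / r, -1), 1))
    rho <- sqrt(positions[, 1]^2 + positions[, 2]^2)
    u <- ifelse(rho > 0, positions[, 1] / rho, 0)
    v <- ifelse(rho > 0, positions[, 2] / rho, 0)
    projection <- cbind(theta * u, theta * v)
  }
  dimnames(positions) <- list(labels, NULL)
  dimnames(projection) <- list(labels, NULL)
  structure(list(labels = as.character(labels), positions = positions,
                 projection = projection),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels\n", length(x$labels)))
  invisible(x)
}

#' Read / write a montage JSON file (`{label: [x, y, z], ...}`)
#' @param path JSON file path.
#' @return [montage()] object.
#' @export
read_montage <- function(path) {
  obj <- jsonlite::fromJSON(path)
  pos <- do.call(rbind, obj)
  montage(names(obj), pos)
}

#' @rdname read_montage
#' @param mon a [montage()].
#' @export
write_montage <- function(mon, path) {
  lst <- lapply(seq_along(mon$labels), function(i) unname(mon$positions[i, ]))
  names(lst) <- mon$labels
  jsonlite::write_json(lst, path, digits = 10)
  invisible(path)
}

#' Generate a geodesic-like scalp montage
#'
#' Channels are laid out on the upper hemisphere along a Fibonacci spiral,
#' which gives an approximately uniform high-density net of configurable
#' size.  Deterministic for a given `n_channels`.
#'
#' @param n_channels number of electrodes (default 64; 256 supported).
#' @return A [montage()].
#' @export
make_montage <- function(n_channels = 64) {
  i <- seq_len(n_channels)
  z <- 1 - 0.95 * (i - 0.5) / n_channels
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(1 - z^2)
  montage(paste0("E", i), cbind(rho * cos(phi), rho * sin(phi), z))
}

#' Channel nearest to a scalp direction
#' @param mon a [montage()].
#' @param xyz length-3 direction vector.
#' @return Channel label.
#' @export
nearest_channel <- function(mon, xyz) {
  xyz <- xyz / sqrt(sum(xyz^2))
  P <- mon$positions / sqrt(rowSums(mon$positions^2))
  mon$labels[which.max(P %*% xyz)]
}

#' Electrode adjacency graph
#'
#' Build a symmetric channel adjacency either by 3D distance (pairs closer
#' than a radius) or by Delaunay triangulation of the 2D projection.
#'
#' @param mon a [montage()].
#' @param method `"distance"` or `"triangulation"`.
#' @param param for `"distance"`, the radius in montage units; defaults to
#'   1.3 x the median nearest-neighbor distance.
#' @return Object of class `adjacency`: list with `labels` and an m x 2
#'   integer `edges` matrix (i < j, no self-edges).
#' @export
build_adjacency <- function(mon, method = c("distance", "triangulation"),
                            param = NULL) {
  method <- match.arg(method)
  n <- length(mon$labels)
  if (n < 1L) stopf("montage has no channels")
  if (method == "distance") {
    D <- as.matrix(stats::dist(mon$positions))
    if (is.null(param)) {
      nn <- apply(D + diag(Inf, n), 1, min)
      param <- 1.3 * stats::median(nn)
    }
    if (param <= 0) stopf("distance radius must be > 0")
    idx <- which(upper.tri(D) & D <= param, arr.ind = TRUE)
    edges <- unname(idx)
  } else {
    if (n < 3L) {
      edges <- if (n == 2L) cbind(1L, 2L) else matrix(integer(), 0, 2)
    } else {
      xy <- mon$projection
      if (anyDuplicated(round(xy, 12)))
        stopf("triangulation requires distinct projected positions")
      ds <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)$delsgs
      edges <- cbind(pmin(ds$ind1, ds$ind2), pmax(ds$ind1, ds$ind2))
      edges <- unique(edges)
    }
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  colnames(edges) <- c("i", "j")
  structure(list(labels = mon$labels, edges = edges, method = method),
            class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("<adjacency> %d channels, %d edges (%s)\n",
              length(x$labels), nrow(x$edges), x$method))
  invisible(x)
}

# neighbor index list, one integer vector per channel
adjacency_list <- function(adj) {
  n <- length(adj$labels)
  nb <- vector("list", n)
  for (k in seq_len(n)) nb[[k]] <- integer()
  if (nrow(adj$edges)) {
    for (r in seq_len(nrow(adj$edges))) {
      i <- adj$edges[r, 1]; j <- adj$edges[r, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}
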