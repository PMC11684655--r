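#' Surface-to-volume ratio of a compartment
#'
#' For a sphere the full surface is used (3/r). For a cylinder only the
#' lateral surface counts by default (2/r), the thin-process limit in which
#' the ER-to-cytosol volume relation was originally fitted; end caps can be
#' included with `lateral_only = FALSE`.
#'
#' @param radius radius in micrometres.
#' @param shape `"sphere"` or `"cylinder"`.
#' @param length cylinder length in micrometres (ignored for spheres).
#' @param lateral_only logical; count only the lateral cylinder surface.
#' @return surface-to-volume ratio in 1/micrometre.
#' @export
#' @examples
#' surface_to_volume(2, "cylinder")    # 1
#' surface_to_volume(20, "sphere")     # 0.15
surface_to_volume <- function(radius, shape = c("cylinder", "sphere"),
                              length = 1, lateral_only = TRUE) {
  shape <- match.arg(shape)
  if (any(radius <= 0)) stop("invalid geometry: radius must be positive")
  if (shape == "sphere") return(3 / radius)
  if (any(length <= 0)) stop("invalid geometry: cylinder length must be positive")
  if (lateral_only) 2 / radius else 2 / radius + 2 / length
}

#' ER-to-cytosol volume ratio
#'
#' The ratio between endoplasmic-reticulum and cytosolic volume decreases
#' with the surface-to-volume ratio of a compartment:
#' `r_ER = a * exp(-(b * av)^c)`. Thick compartments (small `av`) approach
#' the ceiling `a`; fine processes have a vanishing ER share, which is what
#' switches the dominant calcium mechanism from IP3-receptor release to
#' NCX-mediated entry along a tapering process.
#'
#' @param av surface-to-volume ratio (1/micrometre), non-negative.
#' @param a dimensionless ceiling (default 0.15).
#' @param b length constant in micrometres (default 0.073).
#' @param c exponent (default 2.34).
#' @return dimensionless ratio in (0, a].
#' @export
er_volume_ratio <- function(av, a = 0.15, b = 0.073, c = 2.34) {
  if (any(av < 0)) stop("invalid geometry: surface-to-volume ratio must be >= 0")
  a * exp(-(b * av)^c)
}

compartment_volume <- function(shape, radius, length) {
  ifelse(shape == "sphere", 4 / 3 * pi * radius^3, pi * radius^2 * length)
}

compartment_area <- function(shape, radius, length, lateral_only = TRUE) {
  ifelse(shape == "sphere", 4 * pi * radius^2,
         if (lateral_only) 2 * pi * radius * length
         else 2 * pi * radius * (length + radius))
}

# half-extent along the process axis: half-length for cylinders,
# radius for the somatic sphere
half_extent <- function(shape, radius, length) {
  ifelse(shape == "sphere", radius, length / 2)
}

# Monotone taper from 2 um (soma-adjacent) to 0.0625 um (tip) in two
# geometric segments, placing the 0.5 um regime boundary -- below which
# the NCX-dominated calcium mechanism takes over from the IP3R/ER one --
# at the transition into the distal set (positions 5-7).
default_radius_schedule <- function() {
  c(2 * 2^-(0:4 / 2), 0.1, 0.08, 0.0625)
}

region_from_position <- function(pos) {
  # pos: number of cylinder compartments between this one and the soma
  # (0 for a compartment attached to the soma), following the per-arm
  # colour blocks: 2 proximal, 3 intermediate, 3 distal
  ifelse(pos <= 1, "proximal", ifelse(pos <= 4, "intermediate", "distal"))
}

new_morphology <- function(comp) {
  stopifnot(is.data.frame(comp))
  rownames(comp) <- NULL
  m <- structure(list(compartments = comp), class = "astro_morphology")
  validate_morphology(m)
  m
}

#' Validate a morphology
#'
#' Checks the structural invariants of a compartment tree: unique contiguous
#' ids starting at 1, a single spherical root (the soma, id 1), positive
#' geometry, and an acyclic connected parent structure.
#'
#' @param morph an `astro_morphology` object.
#' @return the morphology, invisibly; errors describe the first violation.
#' @export
validate_morphology <- function(morph) {
  comp <- morph$compartments
  need <- c("id", "shape", "radius", "length", "region", "parent")
  if (!all(need %in% names(comp))) stop("morphology: missing columns")
  n <- nrow(comp)
  if (n == 0L) stop("morphology: no compartments")
  if (!identical(as.integer(comp$id), seq_len(n)))
    stop("morphology: ids must be unique and contiguous from 1")
  if (any(comp$radius <= 0)) stop("invalid geometry: radius must be positive")
  cyl <- comp$shape == "cylinder"
  if (any(comp$length[cyl] <= 0))
    stop("invalid geometry: cylinder length must be positive")
  roots <- which(is.na(comp$parent))
  if (length(roots) != 1L) stop("morphology: exactly one root required")
  if (roots != 1L || comp$shape[1] != "sphere")
    stop("morphology: root must be the somatic sphere with id 1")
  p <- comp$parent
  if (any(!is.na(p) & (p < 1 | p > n | p == comp$id)))
    stop("morphology: parent ids out of range")
  # acyclicity + connectivity: walk each node to the root
  for (i in seq_len(n)[-1]) {
    seen <- logical(n); j <- i
    while (!is.na(comp$parent[j])) {
      if (seen[j]) stop("morphology: cycle detected")
      seen[j] <- TRUE
      j <- comp$parent[j]
    }
    if (j != 1L) stop("morphology: disconnected compartment ", i)
  }
  invisible(morph)
}

#' @export
print.astro_morphology <- function(x, ...) {
  comp <- x$compartments
  cat("astro_morphology: ", nrow(comp), " compartments\n", sep = "")
  cat("  soma radius: ", comp$radius[1], " um; tips: ",
      paste(comp$id[!comp$id %in% comp$parent], collapse = ", "), "\n", sep = "")
  tab <- table(comp$region)
  cat("  regions: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Build one of the template astrocyte morphologies
#'
#' All templates share a spherical soma (radius 20 um) and unit-length
#' cylindrical process compartments whose radii taper geometrically from
#' 2 um (attached to the soma) to 0.0625 um (most distal), over eight
#' compartments per soma-to-tip path.
#'
#' * `unipolar`: soma (1) + one process (2-9).
#' * `bipolar`: soma (1) + lower process (2-9) + upper process (10-17).
#' * `bifurcated_terminal`: soma (1) + primary process (2-4) that splits into
#'   a lower (5-9) and an upper (10-14) secondary process.
#'
#' @param kind template name.
#' @param radius_schedule optional vector of 8 process radii (um), tapering
#'   from 2 to 0.0625; the default is a geometric taper.
#' @param soma_radius soma radius in um.
#' @param compartment_length cylinder length in um.
#' @param primary_length number of primary-process compartments in the
#'   bifurcated-terminal template (default 3).
#' @return an `astro_morphology`.
#' @export
#' @examples
#' m <- build_morphology("unipolar")
#' subset(m$compartments, region == "distal")$id   # 7 8 9
build_morphology <- function(kind = c("unipolar", "bipolar",
                                      "bifurcated_terminal"),
                             radius_schedule = NULL,
                             soma_radius = 20, compartment_length = 1,
                             primary_length = 3L) {
  kind <- match.arg(kind)
  sched <- radius_schedule %||% default_radius_schedule()
  if (length(sched) != 8L || any(sched <= 0) || is.unsorted(rev(sched)))
    stop("malformed radius schedule: need 8 positive tapering radii")
  soma <- data.frame(id = 1L, shape = "sphere", radius = soma_radius,
                     length = NA_real_, region = "soma", parent = NA_integer_,
                     stringsAsFactors = FALSE)
  arm <- function(ids, positions, parents) {
    data.frame(id = ids, shape = "cylinder", radius = sched[positions + 1L],
               length = compartment_length,
               region = region_from_position(positions),
               parent = parents, stringsAsFactors = FALSE)
  }
  comp <- switch(kind,
    unipolar = rbind(soma, arm(2:9, 0:7, 1:8)),
    bipolar = rbind(soma,
                    arm(2:9, 0:7, 1:8),
                    arm(10:17, 0:7, c(1L, 10:16))),
    bifurcated_terminal = {
      np <- as.integer(primary_length)
      if (np < 1L || np > 5L) stop("malformed primary process length")
      prim_ids <- seq(2L, 1L + np)
      low_ids <- seq(2L + np, 6L + np)
      up_ids <- seq(7L + np, 11L + np)
      rbind(soma,
            arm(prim_ids, seq_len(np) - 1L, c(1L, prim_ids[-np])),
            arm(low_ids, np:(np + 4L), c(prim_ids[np], low_ids[-5L])),
            arm(up_ids, np:(np + 4L), c(prim_ids[np], up_ids[-5L])))
    })
  new_morphology(comp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjacent compartment pairs
#' @param morph an `astro_morphology`.
#' @return two-column integer matrix of parent-child pairs.
#' @export
adjacency_pairs <- function(morph) {
  comp <- morph$compartments
  child <- comp$id[!is.na(comp$parent)]
  cbind(parent = comp$parent[child], child = child)
}

#' Diffusive coupling strength between two adjacent compartments
#'
#' `F(j <- k) = D * A_c / (V_j * delta)` in 1/s, where `A_c` is the
#' cross-sectional contact area `pi * min(r_j, r_k)^2` and `delta` the
#' centre-to-centre distance (sum of half-lengths; half-diameter for the
#' soma). The form satisfies volume-weighted reciprocity
#' `V_j F(j<-k) = V_k F(k<-j)`, so diffusion conserves total mass; because
#' the somatic volume is large, soma-directed couplings are much weaker
#' than process-process couplings, making the soma a sink.
#'
#' @param morph an `astro_morphology`.
#' @param j,k adjacent compartment ids; the returned rate is the rate of
#'   change of compartment `j` per unit concentration difference `[X]_k - [X]_j`.
#' @param D diffusion coefficient in um^2/s.
#' @return coupling strength in 1/s.
#' @export
coupling_strength <- function(morph, j, k, D, contact = c("min", "mean")) {
  contact <- match.arg(contact)
  comp <- morph$compartments
  if (!(isTRUE(comp$parent[j] == k) || isTRUE(comp$parent[k] == j)))
    stop("topology error: compartments ", j, " and ", k, " are not adjacent")
  r_c <- if (contact == "mean") mean(c(comp$radius[j], comp$radius[k]))
         else min(comp$radius[j], comp$radius[k])
  # the soma's large radius is not a process cross-section; cap the contact
  # radius at the largest process radius involved
  r_c <- min(r_c, max(comp$radius[j][comp$shape[j] != "sphere"],
                      comp$radius[k][comp$shape[k] != "sphere"],
                      min(comp$radius[c(j, k)])))
  a_c <- pi * r_c^2
  delta <- half_extent(comp$shape[j], comp$radius[j], comp$length[j]) +
           half_extent(comp$shape[k], comp$radius[k], comp$length[k])
  v_j <- compartment_volume(comp$shape[j], comp$radius[j], comp$length[j])
  D * a_c / (v_j * delta)
}

#' Coupling matrix for one species
#'
#' @param morph an `astro_morphology`.
#' @param D diffusion coefficient in um^2/s.
#' @return square matrix `M` with `M[j, k] = F(j <- k)` for adjacent pairs
#'   and 0 elsewhere.
#' @export
coupling_matrix <- function(morph, D) {
  n <- nrow(morph$compartments)
  M <- matrix(0, n, n)
  prs <- adjacency_pairs(morph)
  for (r in seq_len(nrow(prs))) {
    j <- prs[r, 1]; k <- prs[r, 2]
    M[j, k] <- coupling_strength(morph, j, k, D)
    M[k, j] <- coupling_strength(morph, k, j, D)
  }
  M
}

#' Read a morphology from an SWC file
#'
#' Seven-column SWC dialect (`id type x y z radius parent`); `#` starts a
#' comment. Cylinder lengths are reconstructed from inter-node distances;
#' region labels are re-derived from the number of cylinder compartments
#' between each node and the soma.
#'
#' @param path file path.
#' @return an `astro_morphology`.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("SWC parse error: no compartments")
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad))
    stop("SWC parse error at line ", lineno[bad[1]], ": expected 7 columns")
  tab <- do.call(rbind, lapply(fields, as.numeric))
  if (anyNA(tab))
    stop("SWC parse error: non-numeric field")
  id <- as.integer(tab[, 1]); parent <- as.integer(tab[, 7])
  o <- order(id)
  tab <- tab[o, , drop = FALSE]; id <- id[o]; parent <- parent[o]
  if (!identical(id, seq_along(id)))
    stop("SWC parse error: ids must be contiguous from 1")
  parent[parent == -1] <- NA_integer_
  miss <- which(!is.na(parent) & !(parent %in% id))
  if (length(miss))
    stop("SWC parse error at line ", lineno[o[miss[1]]],
         ": unknown parent id ", parent[miss[1]])
  xyz <- tab[, 3:5, drop = FALSE]
  len <- rep(NA_real_, length(id))
  for (i in seq_along(id)[!is.na(parent)])
    len[i] <- sqrt(sum((xyz[i, ] - xyz[parent[i], ])^2))
  shape <- ifelse(is.na(parent), "sphere", "cylinder")
  # position = number of cylinder ancestors
  pos <- integer(length(id))
  for (i in seq_along(id)) {
    p <- parent[i]; cnt <- -1L
    while (!is.na(p)) { cnt <- cnt + 1L; p <- parent[p] }
    pos[i] <- max(cnt, 0L)
  }
  region <- ifelse(is.na(parent), "soma", region_from_position(pos))
  new_morphology(data.frame(id = id, shape = shape, radius = tab[, 6],
                            length = len, region = region, parent = parent,
                            stringsAsFactors = FALSE))
}

#' Write a morphology to an SWC file
#'
#' Nodes are laid out in the plane so that the distance between a node and
#' its parent equals the compartment length (branches are fanned out in y),
#' making [read_swc()] an exact inverse.
#'
#' @param morph an `astro_morphology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  comp <- morph$compartments
  n <- nrow(comp)
  x <- y <- numeric(n)
  kids <- split(comp$id[!is.na(comp$parent)],
                comp$parent[!is.na(comp$parent)])
  # depth-first placement; each branch after the first is offset in y
  offset <- setNames(numeric(n), as.character(seq_len(n)))
  for (i in seq_len(n)[-1]) {
    p <- comp$parent[i]
    sibs <- kids[[as.character(p)]]
    rank <- match(i, sibs) - 1L
    dx <- comp$length[i]
    dy <- rank * 1e-6  # disambiguate siblings without changing distances
    nrm <- sqrt(dx^2 + dy^2)
    x[i] <- x[p] + comp$length[i] * dx / nrm
    y[i] <- y[p] + comp$length[i] * dy / nrm
  }
  type <- ifelse(comp$shape == "sphere", 1L, 7L)
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   comp$id, type, x, y, 0, comp$radius,
                   ifelse(is.na(comp$parent), -1L, comp$parent))
  writeLines(c("# SWC morphology (id type x y z radius parent)", lines), path)
  invisible(path)
}
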