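#' Read and write cell masks as multi-page TIFF
#'
#' One page per z-plane; nonzero pixels are foreground.  TIFF pages are
#' stored row-major (row = y), so pages are transposed into the package's
#' \code{[x, y, z]} convention.
#'
#' @param path TIFF file path.
#' @param voxel_size,name passed to \code{\link{cell_support}}.
#' @return \code{read_mask}: a \code{\link{cell_support}}.
#' @export
read_mask <- function(path, voxel_size = c(1, 1, 1), name = basename(path)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # collapse any channel axis
    t(p) > 0
  })
  if (!any(vapply(pages, any, logical(1)))) stop("empty mask in ", path)
  mask <- array(FALSE, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) mask[, , k] <- pages[[k]]
  cell_support(mask, voxel_size = voxel_size, name = name)
}

#' @rdname read_mask
#' @param cell a \code{\link{cell_support}} to write.
#' @export
write_mask <- function(cell, path) {
  pages <- lapply(seq_len(cell$dim[3]),
                  function(k) t(cell$mask[, , k]) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read / write event tables
#'
#' CSV with header \code{x,y,z,w}; coordinates in pixels / plane indices,
#' 0-based.  A missing \code{w} column defaults to unit weights (logged
#' once).
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{x, y, z, w}.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(ev)))
    stop("events file ", path, " lacks columns: ",
         paste(setdiff(need, names(ev)), collapse = ", "))
  if (!"w" %in% names(ev)) {
    message("no 'w' column in ", basename(path), "; using unit weights")
    ev$w <- 1
  }
  ev[, c("x", "y", "z", "w")]
}

#' @rdname read_events
#' @param events data.frame with columns \code{x, y, z[, w]}.
#' @export
write_events <- function(events, path) {
  if (!"w" %in% names(events)) events$w <- 1
  write_num_csv(events[, c("x", "y", "z", "w")], path)
  invisible(path)
}

# numeric output is written with 12 significant digits: stable diffs while
# keeping CSV round trips lossless to 1e-9 absolute on pixel-scale values
write_num_csv <- function(df, path) {
  for (cl in names(df))
    if (is.numeric(df[[cl]])) df[[cl]] <- sprintf("%.12g", df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read trajectories from CSV or TrackMate-style XML
#'
#' CSV format: columns \code{track_id, t, x, y, z}.  XML format: a
#' TrackMate-style document with \code{Spot} elements (\code{ID},
#' \code{POSITION_X/Y/Z}, \code{FRAME}) and per-track \code{Edge} elements
#' (\code{SPOT_SOURCE_ID}, \code{SPOT_TARGET_ID}); the spot order of each
#' track is reconstructed from the edge topology.
#'
#' @param path file path (\code{.csv} or \code{.xml}).
#' @param dt seconds per frame, attached to every trajectory.
#' @return list of \code{\link{trajectory}} objects, named by track id.
#' @export
read_tracks <- function(path, dt = 1) {
  if (grepl("\\.xml$", path, ignore.case = TRUE))
    return(read_tracks_xml(path, dt))
  df <- utils::read.csv(path)
  need <- c("track_id", "t", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("tracks file ", path, " lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- lapply(split(df, df$track_id), function(g) {
    g <- g[order(g$t), ]
    trajectory(g$t, g$x, g$y, g$z, id = as.character(g$track_id[1]), dt = dt)
  })
  out[order(names(out))]
}

read_tracks_xml <- function(path, dt = 1) {
  doc <- xml2::read_xml(path)
  spots <- xml2::xml_find_all(doc, ".//Spot")
  if (length(spots) == 0) stop("no Spot elements in ", path)
  sid <- xml2::xml_attr(spots, "ID")
  sx <- as.numeric(xml2::xml_attr(spots, "POSITION_X"))
  sy <- as.numeric(xml2::xml_attr(spots, "POSITION_Y"))
  sz <- as.numeric(xml2::xml_attr(spots, "POSITION_Z"))
  sf <- as.numeric(xml2::xml_attr(spots, "FRAME"))
  sz[is.na(sz)] <- 0
  lookup <- stats::setNames(seq_along(sid), sid)
  tracks <- xml2::xml_find_all(doc, ".//Track")
  out <- list()
  for (tr in tracks) {
    tid <- xml2::xml_attr(tr, "TRACK_ID")
    if (is.na(tid)) tid <- xml2::xml_attr(tr, "name")
    edges <- xml2::xml_find_all(tr, ".//Edge")
    src <- xml2::xml_attr(edges, "SPOT_SOURCE_ID")
    tgt <- xml2::xml_attr(edges, "SPOT_TARGET_ID")
    ids <- unique(c(src, tgt))
    miss <- ids[!ids %in% names(lookup)]
    if (length(miss))
      stop("track ", tid, " references unknown spot(s): ",
           paste(miss, collapse = ", "))
    # order spots along the chain: start at the spot that is never a target
    nxt <- stats::setNames(tgt, src)
    start <- setdiff(src, tgt)
    if (length(start) != 1) {        # fall back to frame order
      ordered <- ids[order(sf[lookup[ids]])]
    } else {
      ordered <- start
      while (!is.na(nxt[ordered[length(ordered)]])) {
        nx <- unname(nxt[ordered[length(ordered)]])
        if (nx %in% ordered) break   # defensive: cyclic edges
        ordered <- c(ordered, nx)
      }
    }
    k <- lookup[ordered]
    out[[tid]] <- trajectory(sf[k], sx[k], sy[k], sz[k], id = tid, dt = dt)
  }
  if (length(out) == 0) stop("no Track elements in ", path)
  out[order(names(out))]
}

#' Write / read a per-axis density table
#'
#' CSV with columns \code{axis, grid, histogram, density}; the histogram
#' column carries the bin density of the bin containing each grid point
#' (a step function aligned with the smoothed density).  A JSON sidecar
#' (same path, \code{.json} extension) stores the bandwidth and sample size.
#'
#' @param d a \code{density1d}.
#' @param path CSV file path.
#' @param axis axis label stored in the file.
#' @export
write_density <- function(d, path, axis = d$support) {
  h <- d$histogram
  bi <- pmin(findInterval(d$grid, h$breaks, rightmost.closed = TRUE),
             length(h$density))
  bi[bi < 1] <- 1
  df <- data.frame(axis = axis, grid = d$grid, histogram = h$density[bi],
                   density = d$values)
  write_num_csv(df, path)
  jsonlite::write_json(list(bandwidth = d$bandwidth, n = d$n,
                            support = d$support),
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_density
#' @param support \code{"linear"} or \code{"circular"}; by default inferred
#'   from the grid range.
#' @export
read_density <- function(path, support = NULL) {
  df <- utils::read.csv(path)
  if (is.null(support))
    support <- if (max(df$grid) > 1.5) "circular" else "linear"
  density1d(support = support, grid = df$grid, values = df$density,
            histogram = list(breaks = numeric(0), mids = df$grid,
                             weight = df$histogram, density = df$histogram),
            bandwidth = NA_real_, n = NA_integer_)
}

#' Load a study configuration
#'
#' YAML (or JSON) document mapping condition labels to lists of experiment
#' entries.  Each entry names a mask TIFF, an events CSV, and the reference
#' \code{origin: [x, y, z]} and \code{direction: [dx, dy]}.  Optional
#' top-level \code{parameters} override grid sizes, bin counts and the seed.
#'
#' @param path YAML or JSON file.
#' @return a validated list of class \code{study_config}.
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg$conditions) || length(cfg$conditions) < 1)
    stop("study config has no conditions")
  if (anyDuplicated(names(cfg$conditions)))
    stop("duplicate condition labels")
  base <- dirname(normalizePath(path))
  for (cond in names(cfg$conditions)) {
    for (i in seq_along(cfg$conditions[[cond]])) {
      e <- cfg$conditions[[cond]][[i]]
      for (f in c("mask", "events")) {
        if (is.null(e[[f]])) stop("condition '", cond, "' entry ", i,
                                  " lacks '", f, "'")
        p <- e[[f]]
        if (!file.exists(p)) p <- file.path(base, p)
        if (!file.exists(p)) stop("missing file: ", e[[f]])
        cfg$conditions[[cond]][[i]][[f]] <- p
      }
      if (is.null(e$origin) || length(unlist(e$origin)) != 3)
        stop("condition '", cond, "' entry ", i, " needs origin [x, y, z]")
      if (is.null(e$direction)) cfg$conditions[[cond]][[i]]$direction <- c(1, 0)
    }
  }
  structure(cfg, class = "study_config")
}

#' Run a full condition-comparison study
#'
#' End-to-end orchestration: for every experiment the mask and events are
#' loaded, events are expressed in shape-normalized cylindrical coordinates,
#' and the radial, angular and depth densities are estimated; per axis, the
#' pairwise distance matrix (EMD on linear axes, circular EMD on the angular
#' axis), the per-experiment condition differences and the one-sided
#' signed-rank p value are computed.  Deterministic given the configuration.
#'
#' @param config a \code{\link{read_study_config}} result or a path to one.
#' @return an object of class \code{condition_study}: list with
#'   \code{experiments} (labels, conditions), \code{densities} (per axis),
#'   \code{differences} (per axis data.frames), \code{p_values} (per axis).
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  prm <- config$parameters
  vx <- if (!is.null(prm$voxel_size)) unlist(prm$voxel_size) else c(1, 1, 1)
  ids <- character(0); conds <- character(0)
  dens <- list(radius = list(), angle = list(), depth = list())
  errors <- character(0)
  for (cond in names(config$conditions)) {
    for (i in seq_along(config$conditions[[cond]])) {
      e <- config$conditions[[cond]][[i]]
      id <- if (!is.null(e$id)) e$id else sprintf("%s_%02d", cond, i)
      res <- tryCatch({
        cell <- read_mask(e$mask, voxel_size = vx)
        ev <- read_events(e$events)
        if (!is.null(e$weights) && identical(e$weights, "none")) ev$w <- 1
        fr <- reference_frame(unlist(e$origin), unlist(e$direction))
        S <- to_cylindrical(ev, fr, cell)
        lapply(c(radius = "radius", angle = "angle", depth = "depth"),
               function(ax) weighted_density(S, ax,
                                             K = prm$grid_size[[ax]],
                                             bins = prm$bins[[ax]]))
      }, error = function(err)
        paste0("experiment '", id, "' (densities): ", conditionMessage(err)))
      if (is.character(res)) { errors <- c(errors, res); next }
      ids <- c(ids, id); conds <- c(conds, cond)
      for (ax in names(dens)) dens[[ax]][[id]] <- res[[ax]]
    }
  }
  if (length(errors)) stop(paste(errors, collapse = "\n"))
  diffs <- lapply(dens, function(dl)
    condition_difference(dl, conds))
  pvals <- lapply(diffs, function(cd)
    as.numeric(suppressWarnings(wilcoxon_condition_test(cd$delta))))
  structure(list(experiments = data.frame(id = ids, condition = conds,
                                          stringsAsFactors = FALSE),
                 densities = dens, differences = diffs, p_values = pvals),
            class = "condition_study")
}

#' @export
print.condition_study <- function(x, ...) {
  cat("<condition_study> ", nrow(x$experiments), " experiments, ",
      length(unique(x$experiments$condition)), " conditions\n", sep = "")
  for (ax in names(x$p_values))
    cat(sprintf("  %-7s p = %.6g%s\n", ax, x$p_values[[ax]],
                if (x$p_values[[ax]] < 0.05) " *" else ""))
  cat("  (per-axis p values, no multiple-testing correction)\n")
  invisible(x)
}

#' Write a study report to disk
#'
#' Per-axis distance matrices and condition differences as CSV, per-axis p
#' values as JSON, per-experiment density tables, and one overlay figure per
#' axis (all experiment densities colored by condition, over the pooled
#' histogram outline).
#'
#' @param study a \code{\link{run_study}} result.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conds <- study$experiments$condition
  ucond <- unique(conds)
  pal <- stats::setNames(grDevices::hcl.colors(max(length(ucond), 3),
                                               "Dark 3")[seq_along(ucond)],
                         ucond)
  for (ax in names(study$differences)) {
    dl <- study$densities[[ax]]
    grDevices::png(file.path(dir, paste0("densities_", ax, ".png")),
                   width = 900, height = 600)
    ymax <- max(vapply(dl, function(d) max(d$values), numeric(1)))
    graphics::plot(NA, xlim = range(dl[[1]]$grid), ylim = c(0, ymax),
                   xlab = ax, ylab = "density",
                   main = paste0(ax, " (p = ",
                                 signif(study$p_values[[ax]], 3), ")"))
    for (i in seq_along(dl)) {
      d <- dl[[i]]
      h <- d$histogram
      graphics::rect(h$breaks[-length(h$breaks)], 0, h$breaks[-1], h$density,
                     border = grDevices::adjustcolor(pal[conds[i]], 0.25))
      graphics::lines(d$grid, d$values, col = pal[conds[i]], lwd = 2)
    }
    graphics::legend("topright", legend = ucond, lwd = 2,
                     col = pal[ucond], bty = "n")
    grDevices::dev.off()
  }
  for (ax in names(study$differences)) {
    cd <- study$differences[[ax]]
    dm <- attr(cd, "distance_matrix")
    dimnames(dm) <- list(cd$experiment, cd$experiment)
    utils::write.csv(round(dm, 9), file.path(dir, paste0("distances_", ax, ".csv")))
    write_num_csv(cd, file.path(dir, paste0("differences_", ax, ".csv")))
    for (id in names(study$densities[[ax]]))
      write_density(study$densities[[ax]][[id]],
                    file.path(dir, paste0("density_", ax, "_", id, ".csv")),
                    axis = ax)
  }
  jsonlite::write_json(study$p_values, file.path(dir, "p_values.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write an entropy map as a float TIFF
#'
#' Entropy values are written as a 32-bit float image on the mask's plane
#' grid; background voxels carry the minimum entropy.
#'
#' @param em an \code{\link{entropy_map}}.
#' @param cell the \code{\link{cell_support}} the map was computed on.
#' @param path TIFF file path.
#' @export
write_entropy_map <- function(em, cell, path) {
  pl <- cell$mask[, , attr(em, "plane") + 1]
  img <- matrix(min(em$entropy), nrow(pl), ncol(pl))
  img[cbind(em$x + 1, em$y + 1)] <- em$entropy
  rng <- range(img)
  scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  tiff::writeTIFF(t(scaled), path, bits.per.sample = 32L)
  jsonlite::write_json(list(min = rng[1], max = rng[2],
                            argmax = attr(em, "argmax"),
                            step = attr(em, "step")),
                       sub("\\.tiff?$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
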