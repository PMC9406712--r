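# File interchange: multipage TIFF stacks with JSON sidecars carrying the
# physical metadata (pixel size, medium RI, linear intensity scaling), CSV
# tables, YAML run configuration.

sidecar_path <- function(path) paste0(path, ".json")

write_stack_tiff <- function(mats, path, meta, bits = 32L) {
  rng <- range(unlist(lapply(mats, range)))
  off <- rng[1]
  sc <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  pages <- lapply(mats, function(m) (m - off) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  meta$scale <- sc
  meta$offset <- off
  meta$n_pages <- length(mats)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mats <- lapply(pages, function(p) p * meta$scale + meta$offset)
  list(pages = mats, meta = meta)
}

#' Write / read a tomogram as multipage TIFF + JSON sidecar
#'
#' Pages are slices along the first array axis; the sidecar records voxel
#' size, medium RI and the linear intensity scaling. 32-bit storage
#' round-trips to single precision.
#'
#' @param t a [tomogram()].
#' @param path output `.tif` path (sidecar written at `path + ".json"`).
#' @return `path` ([write_tomogram()]); a [tomogram()] ([read_tomogram()]).
#' @export
write_tomogram <- function(t, path) {
  stopifnot(inherits(t, "tomogram"))
  d <- dim(t$values)
  mats <- lapply(seq_len(d[1]), function(i) t$values[i, , ])
  write_stack_tiff(mats, path,
                   list(kind = "tomogram", voxel_size = t$voxel_size,
                        medium_ri = t$medium_ri))
}

#' @rdname write_tomogram
#' @export
read_tomogram <- function(path) {
  st <- read_stack_tiff(path)
  d2 <- dim(st$pages[[1]])
  vol <- array(0, c(length(st$pages), d2))
  for (i in seq_along(st$pages)) vol[i, , ] <- st$pages[[i]]
  tomogram(vol, voxel_size = st$meta$voxel_size,
           medium_ri = st$meta$medium_ri)
}

#' Write / read a hologram stack as multipage TIFF + JSON sidecar
#'
#' 16-bit storage with the linear scaling recorded in the sidecar.
#'
#' @param holograms list of [hologram()] frames.
#' @param path output `.tif` path.
#' @return `path` (writer); list of [hologram()] (reader).
#' @export
write_hologram_stack <- function(holograms, path) {
  write_stack_tiff(lapply(holograms, `[[`, "intensity"), path,
                   list(kind = "hologram",
                        pixel_pitch = holograms[[1]]$pixel_pitch),
                   bits = 16L)
}

#' @rdname write_hologram_stack
#' @export
read_hologram_stack <- function(path) {
  st <- read_stack_tiff(path)
  lapply(seq_along(st$pages), function(i)
    hologram(pmax(st$pages[[i]], 0), st$meta$pixel_pitch, i))
}

#' Write / read a QPM stack as multipage TIFF + JSON sidecar
#'
#' @param qpms list of [qpm()] frames.
#' @param path output `.tif` path.
#' @return `path` (writer); list of [qpm()] (reader).
#' @export
write_qpm_stack <- function(qpms, path) {
  write_stack_tiff(lapply(qpms, `[[`, "phase"), path,
                   list(kind = "qpm", pixel_pitch = qpms[[1]]$pixel_pitch))
}

#' @rdname write_qpm_stack
#' @export
read_qpm_stack <- function(path) {
  st <- read_stack_tiff(path)
  lapply(seq_along(st$pages), function(i)
    qpm(st$pages[[i]], st$meta$pixel_pitch, i))
}

#' Run configuration
#'
#' Bundles the optical, flow, phantom and solver settings plus the master
#' seed; fully serializable to YAML so a run is reproducible from its
#' archived configuration.
#'
#' @param optical an [optical_config()].
#' @param flow a [flow_spec()].
#' @param phantom a [phantom_spec()].
#' @param hotv an [hotv_config()].
#' @param seed master seed.
#' @param frame_size camera frame side, pixels.
#' @param crop_size tomographic crop, micrometres.
#' @param solver default reconstruction solver name.
#' @return An object of class `run_config`.
#' @export
run_config <- function(optical = optical_config(), flow = flow_spec(),
                       phantom = phantom_spec(), hotv = hotv_config(),
                       seed = 1L, frame_size = 192L, crop_size = 12,
                       solver = "hotv-2") {
  structure(list(optical = optical, flow = flow, phantom = phantom,
                 hotv = hotv, seed = as.integer(seed),
                 frame_size = as.integer(frame_size),
                 crop_size = crop_size, solver = solver),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run config (seed", x$seed, "):\n")
  print(x$optical); print(x$flow); print(x$phantom); print(x$hotv)
  cat(sprintf("  frame %d px, crop %g um, solver %s\n", x$frame_size,
              x$crop_size, x$solver))
  invisible(x)
}

#' Write / read a run configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `path` (writer); a [run_config()] (reader).
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(lapply(cfg, function(f) if (is.list(f)) unclass(f) else f),
                   path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(optical = do.call(optical_config,
                               y$optical[names(y$optical) != "pixel_size"]),
             flow = do.call(flow_spec, y$flow),
             phantom = do.call(phantom_spec, y$phantom),
             hotv = do.call(hotv_config, y$hotv),
             seed = y$seed, frame_size = y$frame_size,
             crop_size = y$crop_size, solver = y$solver)
}
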