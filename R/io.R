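## NIfTI-1 + JSON-sidecar readers and writers, study manifest handling,
## and YAML config round-tripping.

SIDECAR_SCHEMA <- 1L

sidecar_path <- function(nii_path) {
  sub("\\.nii(\\.gz)?$", ".json", nii_path)
}

provenance <- function(extra = list()) {
  c(list(tool = "ischemri",
         version = as.character(utils::packageVersion("ischemri")),
         schema = SIDECAR_SCHEMA),
    extra)
}

#' Write an image series as NIfTI-1 with a JSON frame-metadata sidecar
#'
#' @param series an \code{image_series}
#' @param path output path ending in \code{.nii} or \code{.nii.gz}
#' @param extra extra provenance fields for the sidecar
#' @return \code{path}, invisibly
#' @export
write_series <- function(series, path, extra = list()) {
  img <- RNifti::asNifti(series$data,
                         pixdim = c(series$spacing, 1)[1:4])
  RNifti::writeNifti(img, path)
  side <- provenance(c(list(kind = series$kind,
                            n_frames = n_frames(series),
                            spacing = series$spacing),
                       series$frames, extra))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an image series written by \code{write_series}
#'
#' @param path path to the NIfTI file; the sidecar is looked up next to it
#' @return an \code{image_series}
#' @export
read_series <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop_ischemri(sprintf("missing sidecar '%s'", sp), "ischemri_format")
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  known <- c("tool", "version", "schema", "kind", "n_frames", "spacing",
             "subject", "group", "timepoint", "units", "seed", "config_hash")
  frame_keys <- intersect(c("ti", "te", "bval", "role"), names(side))
  unknown <- setdiff(names(side), c(known, frame_keys))
  if (length(unknown))
    warning(sprintf("sidecar has unknown keys (%s); ignoring",
                    paste(unknown, collapse = ", ")))
  img <- RNifti::readNifti(path)
  dat <- array(as.numeric(img), dim = dim(img))
  if (length(dim(dat)) == 3) dim(dat) <- c(dim(dat), 1L)
  nf <- dim(dat)[4]
  if (!is.null(side$n_frames) && side$n_frames != nf)
    stop_ischemri(sprintf("sidecar frame count %d != data frames %d",
                          side$n_frames, nf), "ischemri_consistency")
  frames <- side[frame_keys]
  for (f in frame_keys)
    if (length(frames[[f]]) != nf)
      stop_ischemri(sprintf("sidecar '%s' has %d entries for %d frames",
                            f, length(frames[[f]]), nf),
                    "ischemri_consistency")
  image_series(dat, side$kind %||% "structural",
               spacing = as.numeric(side$spacing %||% RNifti::pixdim(img)[1:3]),
               frames = frames)
}

#' Write a parameter map as float32 NIfTI-1 with a units sidecar
#'
#' @param map a \code{parameter_map}
#' @param path output path
#' @param extra extra provenance fields
#' @return \code{path}, invisibly
#' @export
write_map <- function(map, path, extra = list()) {
  vals <- map$values
  vals[!map$mask] <- NA_real_
  img <- RNifti::asNifti(vals, pixdim = c(map$spacing, 1)[1:4],
                         datatype = "float")
  RNifti::writeNifti(img, path)
  side <- provenance(c(list(kind = map$kind, units = map$units,
                            spacing = map$spacing), extra))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a parameter map written by \code{write_map}
#' @param path path to the NIfTI file
#' @return a \code{parameter_map}
#' @export
read_map <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop_ischemri(sprintf("missing sidecar '%s'", sp), "ischemri_format")
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) < 3) d <- c(d, rep(1L, 3 - length(d)))
  vals <- array(as.numeric(img), dim = d[1:3])
  mask <- is.finite(vals)
  parameter_map(vals, side$kind, mask, as.numeric(side$spacing))
}

#' Write a study bundle to disk
#'
#' Lays the bundle out as one directory per subject-timepoint record with
#' the simulated series, truth maps and masks as NIfTI-1 + sidecars, plus
#' a JSON manifest and the YAML config at the root.
#'
#' @param study a \code{study_bundle}
#' @param dir output directory (created if needed)
#' @return the manifest path, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (rec in study$records) {
    sub <- file.path(dir, sprintf("%s_%s", rec$subject_id, rec$timepoint))
    dir.create(sub, showWarnings = FALSE)
    paths <- list()
    for (k in names(rec$series)) {
      p <- file.path(sub, sprintf("%s.nii.gz", k))
      write_series(rec$series[[k]], p,
                   extra = list(subject = rec$subject_id,
                                group = rec$group, timepoint = rec$timepoint))
      paths[[k]] <- p
    }
    tr <- rec$truth
    for (m in c("t1", "t2", "adc", "cbf")) {
      kind <- c(t1 = "T1", t2 = "T2", adc = "ADC", cbf = "CBF")[[m]]
      pm <- parameter_map(ifelse(tr$masks$brain, tr[[m]], NA_real_),
                          kind, tr$masks$brain, tr$spacing)
      write_map(pm, file.path(sub, sprintf("truth_%s.nii.gz", m)))
    }
    RNifti::writeNifti(RNifti::asNifti(tr$labels * 1,
                                       pixdim = c(tr$spacing, 1)[1:4]),
                       file.path(sub, "labels.nii.gz"))
    entries[[length(entries) + 1L]] <-
      list(subject_id = rec$subject_id, group = rec$group,
           timepoint = rec$timepoint, series = paths)
  }
  manifest <- list(provenance = provenance(list(seed = study$config$seed,
                                                config_hash = object_hash(study$config[
                                                  setdiff(names(study$config), "atlas")]))),
                   groups = names(study$config$groups),
                   records = entries)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_config_yaml(study$config, file.path(dir, "config.yaml"))
  invisible(mp)
}

#' Validate and read a study manifest
#'
#' Checks that every referenced series file and sidecar exists and that
#' each (subject, timepoint, series kind) combination is unique.
#'
#' @param path path to \code{manifest.json}
#' @return the parsed manifest list
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_ischemri(sprintf("manifest '%s' not found", path), "ischemri_format")
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(man$records) == 0)
    stop_ischemri("manifest lists no records", "ischemri_manifest")
  seen <- character()
  for (rec in man$records) {
    for (k in names(rec$series)) {
      key <- paste(rec$subject_id, rec$timepoint, k)
      if (key %in% seen)
        stop_ischemri(sprintf("duplicate series entry: %s", key),
                      "ischemri_manifest")
      seen <- c(seen, key)
      p <- rec$series[[k]]
      if (!file.exists(p))
        stop_ischemri(sprintf("referenced file missing: %s", p),
                      "ischemri_manifest")
      if (!file.exists(sidecar_path(p)))
        stop_ischemri(sprintf("sidecar missing for: %s", p),
                      "ischemri_manifest")
    }
  }
  man
}

#' Write a phantom config as YAML
#' @param config a \code{phantom_config}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_config_yaml <- function(config, path) {
  plain <- config[setdiff(names(config), "atlas")]
  plain$protocol <- unclass(plain$protocol)
  plain$tissues <- as.list(plain$tissues)
  if (!is.null(plain$cells) && nrow(config$cells) > 0)
    plain$cells <- as.list(plain$cells)
  else plain$cells <- NULL
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a phantom config from YAML
#' @param path path to a YAML file written by \code{write_config_yaml}
#' @return a \code{phantom_config}
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  phantom_config(
    groups = y$groups,
    cells = if (!is.null(y$cells)) as.data.frame(y$cells) else NULL,
    tissues = as.data.frame(y$tissues),
    n = unlist(y$n), spacing = unlist(y$spacing),
    s0 = y$s0, snr = y$snr, beta_inv = y$beta_inv,
    lesion = y$lesion,
    subject_cv_healthy = y$subject_cv_healthy,
    protocol = acquisition_protocol(
      ti = unlist(y$protocol$ti),
      n_echoes = y$protocol$n_echoes,
      echo_spacing = y$protocol$echo_spacing,
      b_values = unlist(y$protocol$b_values),
      n_b800 = y$protocol$n_b800,
      alpha = y$protocol$alpha, lambda = y$protocol$lambda,
      casl_averages = y$protocol$casl_averages),
    seed = y$seed)
}

#' Serialize a rigid transform to JSON
#' @param transform a \code{rigid_transform}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path JSON path
#' @return a \code{rigid_transform}
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(j$theta, j$tx, j$ty,
                  fixed_grid = j$fixed_grid, moving_grid = j$moving_grid)
}
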