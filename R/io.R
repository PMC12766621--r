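#' Default parameter tag map
#'
#' Sequence parameters required for Bloch-based conversion do not all have
#' standard DICOM fields; vendors convey them through private tags. The
#' archive written by [write_study()] stores every parameter under a tag
#' address, and [read_study()] resolves them through a tag map so that vendor
#' dialects can be accommodated by remapping.
#'
#' @return named character vector mapping parameter names to tag addresses.
#' @export
default_tag_map <- function() {
  c(flip_angle = "0018,1314", TR = "0018,0080", TE = "0018,0081",
    TS = "0019,1001", TD = "0019,1002", lines_to_center = "0019,1003",
    readout = "0019,1004", acquisition_window = "0019,1005",
    pd_flip_angle = "0019,1006", saturation_efficiency = "0019,1007",
    T2 = "0019,1008", role = "0019,1009", dynamic_interval = "0019,100a",
    trigger_times = "0018,1060", frame_roles = "0019,100b",
    pixel_spacing = "0028,0030", slice_location = "0020,1041",
    contrast_agent = "0018,0010")
}

required_seq_fields <- function() {
  c("flip_angle", "TR", "TE", "TS", "TD", "lines_to_center", "readout",
    "acquisition_window", "role")
}

series_to_sidecar <- function(series, tagmap) {
  tags <- list()
  for (nm in names(tagmap)) {
    val <- switch(nm,
                  trigger_times = series$trigger_times,
                  frame_roles = series$frame_roles,
                  pixel_spacing = series$pixel_spacing,
                  slice_location = series$slice_location,
                  contrast_agent = NULL,
                  series$seq[[nm]])
    if (!is.null(val)) tags[[tagmap[[nm]]]] <- val
  }
  tags
}

sidecar_to_series <- function(tags, frames, tagmap) {
  get_tag <- function(nm) tags[[tagmap[[nm]]]]
  for (nm in c(required_seq_fields(), "trigger_times", "frame_roles"))
    if (is.null(get_tag(nm)))
      stop(sprintf("unresolvable required parameter '%s' (tag %s) in study archive",
                   nm, tagmap[[nm]]))
  seq <- seq_params(
    flip_angle = get_tag("flip_angle"), TR = get_tag("TR"),
    TE = unlist(get_tag("TE")), TS = get_tag("TS"), TD = get_tag("TD"),
    lines_to_center = get_tag("lines_to_center"),
    readout = get_tag("readout"),
    acquisition_window = get_tag("acquisition_window"),
    dynamic_interval = get_tag("dynamic_interval"),
    role = get_tag("role"),
    pd_flip_angle = get_tag("pd_flip_angle") %||% 5,
    saturation_efficiency = get_tag("saturation_efficiency") %||% 1,
    T2 = get_tag("T2") %||% 45)
  trig <- unlist(get_tag("trigger_times"))
  roles <- unlist(get_tag("frame_roles"))
  ord <- order(trig)  # frames are time-ordered regardless of storage order
  dynamic_series(frames = frames[, , ord, drop = FALSE],
                 trigger_times = trig[ord], frame_roles = roles[ord],
                 pixel_spacing = unlist(get_tag("pixel_spacing")) %||% NA_real_,
                 slice_location = get_tag("slice_location") %||% 0,
                 seq = seq)
}

#' Write a study bundle to a self-describing archive
#'
#' Pixel data are stored as NIfTI volumes (one per series, frame as the third
#' dimension); all sequence parameters, frame timing and roles are stored in
#' JSON sidecars under tag addresses (see [default_tag_map()]); ground truth,
#' when present, is written loss-lessly to `truth.json` plus NIfTI maps.
#'
#' @param study a `study_bundle`.
#' @param path directory to create.
#' @param tagmap parameter tag map.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path, tagmap = default_tag_map()) {
  stopifnot(inherits(study, "study_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_series <- function(series, stem) {
    RNifti::writeNifti(series$frames, file.path(path, paste0(stem, ".nii.gz")),
                       datatype = "double")
    jsonlite::write_json(series_to_sidecar(series, tagmap),
                         file.path(path, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  for (s in seq_along(study$myocardial))
    write_series(study$myocardial[[s]], sprintf("myo_%02d", s))
  if (!is.null(study$aif_series)) write_series(study$aif_series, "aif")
  manifest <- list(condition = study$condition,
                   n_slices = length(study$myocardial),
                   has_aif_series = !is.null(study$aif_series),
                   has_ground_truth = !is.null(study$ground_truth))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  gt <- study$ground_truth
  if (!is.null(gt)) {
    scal <- gt[c("times", "t_sr", "sr_frames", "aif", "aif_blood",
                 "aif_plasma", "tissue", "arrival_time")]
    scal$params <- lapply(gt$params, unclass)
    jsonlite::write_json(scal, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    for (s in seq_along(gt$fp_maps)) {
      RNifti::writeNifti(gt$fp_maps[[s]],
                         file.path(path, sprintf("truth_fp_%02d.nii.gz", s)),
                         datatype = "double")
      RNifti::writeNifti(gt$myo_masks[[s]] * 1,
                         file.path(path, sprintf("truth_myo_%02d.nii.gz", s)),
                         datatype = "double")
    }
    RNifti::writeNifti(gt$blood_mask * 1, file.path(path, "truth_blood.nii.gz"),
                       datatype = "double")
  }
  invisible(path)
}

#' Read a study archive
#'
#' Reconstructs a `study_bundle` from a [write_study()] archive: series are
#' grouped by role, frames re-ordered by trigger time (storage order is
#' irrelevant), PD frames identified from the stored roles, and all sequence
#' parameters resolved through the tag map; a missing required parameter is
#' an error naming the field and tag.
#'
#' @param path archive directory.
#' @param tagmap parameter tag map (vendor dialect).
#' @return a `study_bundle`.
#' @export
read_study <- function(path, tagmap = default_tag_map()) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  read_series <- function(stem) {
    img <- RNifti::readNifti(file.path(path, paste0(stem, ".nii.gz")))
    frames <- array(as.numeric(img), dim = dim(img))
    if (length(dim(frames)) > 3)
      stop("unsupported input: 3D multi-frame volumes; 2D multi-slice series required")
    tags <- jsonlite::read_json(file.path(path, paste0(stem, ".json")))
    sidecar_to_series(tags, frames, tagmap)
  }
  myo <- lapply(seq_len(manifest$n_slices),
                function(s) read_series(sprintf("myo_%02d", s)))
  aif <- if (isTRUE(manifest$has_aif_series)) read_series("aif") else NULL
  gt <- NULL
  if (isTRUE(manifest$has_ground_truth)) {
    gt <- jsonlite::read_json(file.path(path, "truth.json"),
                              simplifyVector = TRUE)
    plist <- if (is.data.frame(gt$params))
      lapply(seq_len(nrow(gt$params)), function(i) as.list(gt$params[i, ]))
    else gt$params
    keep <- c("F_p", "v_p", "v_e", "PS", "fermi_A", "fermi_mu", "fermi_k",
              "fermi_offset")
    gt$params <- lapply(plist, function(p) {
      p <- p[intersect(keep, names(p))]
      do.call(kinetic_params, p[!vapply(p, function(x)
        is.null(x) || all(is.na(x)), logical(1))])
    })
    gt$tissue <- if (is.matrix(gt$tissue)) lapply(seq_len(ncol(gt$tissue)), function(i) gt$tissue[, i]) else as.list(gt$tissue)
    fp_files <- sort(list.files(path, "^truth_fp_", full.names = TRUE))
    gt$fp_maps <- lapply(fp_files, function(f) {
      img <- RNifti::readNifti(f); array(as.numeric(img), dim = dim(img))
    })
    myo_files <- sort(list.files(path, "^truth_myo_", full.names = TRUE))
    gt$myo_masks <- lapply(myo_files, function(f) {
      img <- RNifti::readNifti(f); array(as.numeric(img), dim = dim(img)) > 0.5
    })
    bf <- file.path(path, "truth_blood.nii.gz")
    if (file.exists(bf)) {
      img <- RNifti::readNifti(bf)
      gt$blood_mask <- array(as.numeric(img), dim = dim(img)) > 0.5
    }
  }
  structure(list(myocardial = myo, aif_series = aif, ground_truth = gt,
                 condition = manifest$condition), class = "study_bundle")
}
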