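#' Multi-modal volume set
#'
#' One case's four co-registered modality volumes plus an optional
#' integer segmentation.  All five volumes must share one shape and
#' the segmentation may only use the raw BraTS label values
#' {0, 1, 2, 4}.
#'
#' @param case_id case identifier string.
#' @param modalities named list with 3-D arrays `t1`, `t1ce`, `t2`,
#'   `flair`.
#' @param seg optional 3-D integer array of the same shape.
#' @export
volume_set <- function(case_id, modalities, seg = NULL) {
  miss <- setdiff(.modalities, names(modalities))
  if (length(miss))
    stop("missing modalities: ", paste(miss, collapse = ", "))
  shp <- dim(modalities[[.modalities[1]]])
  for (m in .modalities) {
    if (length(dim(modalities[[m]])) != 3)
      stop("modality ", m, " is not a 3-D volume")
    if (!identical(dim(modalities[[m]]), shp))
      stop("modality ", m, " shape differs from t1")
  }
  if (!is.null(seg)) {
    if (!identical(dim(seg), shp))
      stop("segmentation shape differs from the modalities")
    bad <- setdiff(unique(as.integer(seg)), c(0L, 1L, 2L, 4L))
    if (length(bad))
      stop("segmentation contains labels outside {0,1,2,4}: ",
           paste(bad, collapse = ", "))
    storage.mode(seg) <- "integer"
  }
  structure(list(case_id = case_id, modalities = modalities[.modalities],
                 seg = seg, shape = shp),
            class = "volume_set")
}

#' Read a BraTS-style case from disk
#'
#' Accepts either a case directory containing modality-suffixed NIfTI
#' files (`<id>_t1.nii[.gz]`, `_t1ce`, `_t2`, `_flair`, optional
#' `_seg`) or an explicit named list of paths.
#'
#' @param paths case directory or named list/vector with entries `t1`,
#'   `t1ce`, `t2`, `flair` and optionally `seg`.
#' @param case_id case identifier; defaults to the directory name.
#' @return a [volume_set()].
#' @export
read_case <- function(paths, case_id = NULL) {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    dirp <- paths
    if (is.null(case_id)) case_id <- basename(dirp)
    paths <- list()
    for (m in c(.modalities, "seg")) {
      hit <- list.files(dirp, pattern = paste0("_", m, "\\.nii(\\.gz)?$"),
                        full.names = TRUE)
      if (length(hit) == 1) paths[[m]] <- hit
    }
  }
  paths <- as.list(paths)
  miss <- setdiff(.modalities, names(paths))
  if (length(miss))
    stop("missing modality file(s): ", paste(miss, collapse = ", "))
  if (is.null(case_id)) case_id <- "case"
  modalities <- lapply(paths[.modalities], read_nifti)
  seg <- NULL
  if (!is.null(paths$seg)) {
    seg <- read_nifti(paths$seg)
    seg <- array(as.integer(round(seg)), dim(seg))
  }
  volume_set(case_id, modalities, seg)
}

#' Remap raw BraTS labels to contiguous classes
#'
#' Bijection {0,1,2,4} <-> {0,1,2,3}.  `inverse = TRUE` restores the
#' raw convention.
#'
#' @param x integer array of labels.
#' @param inverse map contiguous classes back to raw labels.
#' @export
remap_labels <- function(x, inverse = FALSE) {
  v <- as.integer(x)
  if (inverse) {
    if (any(!v %in% 0:3)) stop("contiguous labels must lie in {0,1,2,3}")
    out <- c(0L, 1L, 2L, 4L)[v + 1L]
  } else {
    if (any(!v %in% c(0L, 1L, 2L, 4L)))
      stop("raw labels must lie in {0,1,2,4}")
    lut <- rep(NA_integer_, 5)
    lut[c(0L, 1L, 2L, 4L) + 1L] <- 0:3
    out <- lut[v + 1L]
  }
  array(out, dim(x) %||% length(v))
}

#' Z-score normalize a volume over brain voxels
#'
#' Zero voxels are treated as background and left at exactly 0; the
#' nonzero (brain) voxels are centered and scaled to unit variance and
#' clipped to `[-5, 5]`.  A constant nonzero volume maps to all zeros
#' (zero-variance guard); an all-zero volume is returned unchanged with
#' a warning.
#'
#' @param volume 3-D numeric array.
#' @return normalized array of the same shape.
#' @export
normalize_volume <- function(volume) {
  if (!all(is.finite(volume))) stop("volume contains non-finite values")
  nz <- volume != 0
  if (!any(nz)) {
    warning("all-zero volume; returned unchanged")
    return(volume)
  }
  v <- volume[nz]
  s <- sd(v)
  out <- volume
  out[nz] <- if (s < 1e-12) 0 else pmin(5, pmax(-5, (v - mean(v)) / s))
  out
}

#' A single preprocessed training slice
#'
#' @param image `(side, side, 4)` array, channel order t1, t1ce, t2,
#'   flair.
#' @param mask integer matrix with contiguous class labels.
#' @param case_id,slice_index provenance.
#' @param n_classes number of classes the mask may use.
#' @export
slice_sample <- function(image, mask, case_id = "case", slice_index = 0L,
                         n_classes = 4L) {
  if (!all(is.finite(image))) stop("slice image must be finite")
  if (any(mask < 0L) || any(mask >= n_classes))
    stop("mask values must lie in [0, n_classes)")
  structure(list(image = image, mask = mask,
                 provenance = list(case_id = case_id,
                                   slice_index = as.integer(slice_index))),
            class = "slice_sample")
}

#' Preprocess a case into training slices
#'
#' Per-volume z-score normalization of each modality, axial slice
#' extraction over a half-open 0-based window, centered edge crop from
#' the native side to `crop_size` (240 -> 192 removes 24 pixels per
#' side), channel-wise stacking of the four modalities, and label
#' remapping {0,1,2,4} -> {0,1,2,3}.
#'
#' @param vs a [volume_set()] (with segmentation, unless
#'   `require_seg = FALSE`, in which case masks are all-background).
#' @param slice_window half-open 0-based axial interval
#'   `c(lo, hi)`; default `c(30, 120)`, i.e. 90 slices.
#' @param crop_size output side length (default 192).
#' @param require_seg error when the segmentation is missing.
#' @return list of [slice_sample()] objects, one per axial index.
#' @export
preprocess_case <- function(vs, slice_window = c(30L, 120L),
                            crop_size = 192L, require_seg = TRUE) {
  stopifnot(inherits(vs, "volume_set"))
  shp <- vs$shape
  lo <- as.integer(slice_window[1]); hi <- as.integer(slice_window[2])
  if (lo < 0L || hi > shp[3] || lo >= hi)
    stop("slice window [", lo, ",", hi, ") exceeds the axial extent 0..",
         shp[3])
  if (crop_size > shp[1] || crop_size > shp[2])
    stop("crop_size ", crop_size, " exceeds the in-plane extent")
  if (is.null(vs$seg) && require_seg)
    stop("case ", vs$case_id, " has no segmentation")
  off1 <- (shp[1] - crop_size) %/% 2L
  off2 <- (shp[2] - crop_size) %/% 2L
  rows <- off1 + seq_len(crop_size)
  cols <- off2 + seq_len(crop_size)
  norm <- lapply(vs$modalities, normalize_volume)
  out <- vector("list", hi - lo)
  for (z in lo:(hi - 1L)) {
    img <- array(0, c(crop_size, crop_size, 4L))
    for (mi in seq_along(.modalities))
      img[, , mi] <- norm[[.modalities[mi]]][rows, cols, z + 1L]
    mask <- if (is.null(vs$seg)) {
      matrix(0L, crop_size, crop_size)
    } else {
      remap_labels(vs$seg[rows, cols, z + 1L])
    }
    out[[z - lo + 1L]] <- slice_sample(img, mask, vs$case_id, z)
  }
  out
}

#' Split case ids into train and test sets
#'
#' Deterministic patient-level split: `round(train_fraction * n)` cases
#' go to training, the rest to test.  Splitting at the case (not
#' slice) level prevents leakage of neighboring slices across the
#' split.
#'
#' @param case_ids character vector of case ids (>= 2).
#' @param train_fraction fraction in (0, 1); default 0.8.
#' @param seed integer RNG seed.
#' @return a `dataset_split` list with `train`, `test` and `seed`.
#' @export
split_cases <- function(case_ids, train_fraction = 0.8, seed = 1L) {
  if (length(case_ids) < 2) stop("need at least 2 cases to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  n <- length(case_ids)
  n_train <- round(train_fraction * n)
  n_train <- max(1L, min(n - 1L, n_train))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  train <- sort(sample(case_ids, n_train))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  structure(list(train = train, test = sort(setdiff(case_ids, train)),
                 seed = as.integer(seed)),
            class = "dataset_split")
}
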