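#' Phantom cohort configuration
#'
#' Describes a cohort of synthetic BraTS-like cases: four co-registered
#' modality volumes (t1, t1ce, t2, flair) with modality-dependent
#' tissue/tumor contrast, a nested tumor labeled with the raw BraTS
#' values {2 outer/edema-like, 1 middle/core-like, 4 inner/enhancing},
#' additive Gaussian noise inside the brain, and exact-zero background.
#'
#' @param shape integer triple; default the BraTS geometry
#'   `c(240, 240, 155)`.  A reduced preset `c(64, 64, 16)` is used in
#'   tests.
#' @param n_cases number of cases.
#' @param tumor_fraction_range range of the tumor fraction of brain
#'   voxels.
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (intensities are on a roughly 0-1 scale).
#' @param seed integer; generation is fully deterministic given
#'   `(seed, case_index)`.
#' @export
phantom_config <- function(shape = c(240L, 240L, 155L), n_cases = 1L,
                           tumor_fraction_range = c(0.02, 0.10),
                           noise_sd = 0.05, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 8L))
    stop("shape must be three integers >= 8")
  if (n_cases < 0) stop("n_cases must be nonnegative")
  tr <- as.numeric(tumor_fraction_range)
  if (length(tr) != 2 || tr[1] > tr[2] || tr[1] <= 0 || tr[2] >= 1)
    stop("tumor_fraction_range must be an interval inside (0, 1)")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(shape = shape, n_cases = as.integer(n_cases),
                 tumor_fraction_range = tr, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

.modalities <- c("t1", "t1ce", "t2", "flair")

# Modality-specific intensity offsets per tumor compartment (raw label),
# chosen so each compartment is separable on at least one channel:
# edema (2) is brightest on flair/t2, the enhancing core (4) on t1ce.
.tumor_contrast <- rbind(
  #          lbl1    lbl2    lbl4
  t1    = c(-0.15, -0.08,  0.10),
  t1ce  = c( 0.15,  0.05,  0.50),
  t2    = c( 0.25,  0.35,  0.15),
  flair = c( 0.30,  0.45,  0.25))

.brain_base <- c(t1 = 0.45, t1ce = 0.50, t2 = 0.40, flair = 0.42)

# Squared normalized radius field for an ellipsoid: center cx (in
# [-1,1] coords), semi-axes ax.  Returned as a full (nx, ny, nz) array.
.ellipsoid_r2 <- function(shape, cx, ax) {
  u <- lapply(1:3, function(i) {
    s <- shape[i]
    (((seq_len(s) - (s + 1) / 2) / (s / 2)) - cx[i])^2 / ax[i]^2
  })
  xy <- outer(u[[1]], u[[2]], "+")
  array(rep(xy, shape[3]), shape) +
    rep(u[[3]], each = shape[1] * shape[2])
}

# Smooth low-frequency texture field in [-1, 1] scale.
.texture_field <- function(shape, n_waves = 3) {
  tex <- array(0, shape)
  grid <- lapply(1:3, function(i) (seq_len(shape[i]) - 1) / shape[i])
  for (k in seq_len(n_waves)) {
    f <- runif(3, 1, 3) * 2 * pi
    ph <- runif(1, 0, 2 * pi)
    lin <- outer(f[1] * grid[[1]], f[2] * grid[[2]], "+")
    lin <- array(rep(lin, shape[3]), shape) +
      rep(f[3] * grid[[3]], each = shape[1] * shape[2])
    tex <- tex + runif(1, 0.3, 0.6) * sin(lin + ph)
  }
  tex / n_waves
}

#' Generate one phantom case
#'
#' Deterministic given `(config$seed, case_index)`: an ellipsoidal
#' brain with smooth per-modality texture, a nested three-compartment
#' tumor entirely inside the brain, additive Gaussian noise restricted
#' to brain voxels and exact-zero background.
#'
#' @param config a [phantom_config()].
#' @param case_index positive integer case number.
#' @return a [volume_set()].
#' @export
generate_phantom_case <- function(config, case_index = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed((config$seed * 100003L + case_index * 7919L) %% 2147483647L)
  shape <- config$shape

  brain_ax <- c(0.80, 0.80, 0.78) + runif(3, -0.03, 0.03)
  brain_r2 <- .ellipsoid_r2(shape, c(0, 0, 0), brain_ax)
  brain <- brain_r2 <= 1
  n_brain <- sum(brain)

  frac <- runif(1, config$tumor_fraction_range[1],
                config$tumor_fraction_range[2])
  # semi-axes scaled so the tumor ellipsoid volume ~ frac * brain volume
  jit <- runif(3, 0.85, 1.15)
  jit <- jit / prod(jit)^(1 / 3)
  tum_ax <- brain_ax * frac^(1 / 3) * jit
  # fit check: tumor must sit strictly inside the brain surface
  margin <- 0.95 - tum_ax / brain_ax
  if (any(margin < 0))
    stop("tumor cannot fit inside the brain at the requested fraction")
  ctr <- runif(3, -1, 1) * margin * brain_ax
  tum_r2 <- .ellipsoid_r2(shape, ctr, tum_ax)

  bidx <- which(brain)
  seg <- array(0L, shape)
  seg[tum_r2 <= 1 & brain] <- 2L         # edema-like outer shell
  seg[tum_r2 <= 0.7^2 & brain] <- 1L     # core-like middle shell
  seg[tum_r2 <= 0.4^2 & brain] <- 4L     # enhancing inner region
  lbl_idx <- lapply(c(1L, 2L, 4L), function(l) which(seg == l))

  tex_b <- .texture_field(shape)[bidx]
  modalities <- list()
  for (m in .modalities) {
    vol <- array(0, shape)
    v <- .brain_base[[m]] + 0.10 * tex_b
    if (config$noise_sd > 0)
      v <- v + rnorm(n_brain, sd = config$noise_sd)
    vol[bidx] <- v
    for (li in 1:3)
      vol[lbl_idx[[li]]] <- vol[lbl_idx[[li]]] + .tumor_contrast[m, li]
    modalities[[m]] <- vol
  }
  volume_set(sprintf("case_%03d", case_index), modalities, seg)
}

#' Write a phantom cohort to disk
#'
#' Writes `config$n_cases` case directories in the layout
#' [read_case()] expects (one directory per case, modality-suffixed
#' `.nii.gz` files plus `_seg`), and a tab-separated manifest of case
#' ids and seeds.
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if missing).
#' @return manifest data frame (case_id, case_index, seed), invisibly.
#' @export
write_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  manifest <- data.frame(case_id = character(), case_index = integer(),
                         seed = integer(), stringsAsFactors = FALSE)
  for (ci in seq_len(config$n_cases)) {
    vs <- generate_phantom_case(config, ci)
    cdir <- file.path(out_dir, vs$case_id)
    dir.create(cdir, showWarnings = FALSE)
    for (m in .modalities)
      write_nifti(vs$modalities[[m]],
                  file.path(cdir, sprintf("%s_%s.nii.gz", vs$case_id, m)),
                  datatype = "float64")
    write_nifti(vs$seg,
                file.path(cdir, sprintf("%s_seg.nii.gz", vs$case_id)),
                datatype = "int16")
    manifest[nrow(manifest) + 1L, ] <- list(vs$case_id, ci, config$seed)
  }
  write.table(manifest, file.path(out_dir, "manifest.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
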