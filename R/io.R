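# HDF5 container and NIfTI map output.  Complex arrays are stored as paired
# real/imag float64 datasets so the container is readable from any language.

h5_write_complex <- function(x, path, group) {
  rhdf5::h5createGroup(path, group)
  rhdf5::h5write(Re(x), path, paste0(group, "/real"))
  rhdf5::h5write(Im(x), path, paste0(group, "/imag"))
}

h5_read_complex <- function(path, group) {
  re <- rhdf5::h5read(path, paste0(group, "/real"))
  im <- rhdf5::h5read(path, paste0(group, "/imag"))
  array(complex(real = re, imaginary = im), dim = dim(re))
}

h5_has <- function(ls_df, name) name %in% paste0(ls_df$group, "/", ls_df$name) |
  name %in% paste0(sub("^/$", "", ls_df$group), "/", ls_df$name)

#' Save / load a dataset container
#'
#' HDF5 layout: `/kspace/{real,imag}`; `/sampling/mask` (Cartesian,
#' Mx x My x L uint8) or `/sampling/{traj,spoke_of_sample,time_of_sample,
#' spoke_angle_deg}` (radial, trajectory in cycles/sample); `/sens/{real,
#' imag}`; optional `/sequence/{fa_deg,tr_ms,te_ms,inversion,rf_phase_deg}`;
#' optional `/truth/*`; scalar metadata as attributes of `/meta`.
#'
#' @param ds an `hdprost_dataset` (see [simulate_mrf_kspace()],
#'   [simulate_mt_kspace()]).
#' @param path HDF5 file path.
#' @param overwrite replace an existing file.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(ds, path, overwrite = TRUE) {
  stopifnot(inherits(ds, "hdprost_dataset"))
  if (file.exists(path)) {
    if (!overwrite) stop("file exists: ", path, call. = FALSE)
    unlink(path)
  }
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5_write_complex(ds$kspace, path, "kspace")
  h5_write_complex(ds$sens, path, "sens")
  rhdf5::h5createGroup(path, "sampling")
  if (inherits(ds$sampling, "radial_sampling")) {
    s <- ds$sampling
    rhdf5::h5write(s$coords, path, "sampling/traj")
    rhdf5::h5write(as.integer(s$spoke_of_sample), path,
                   "sampling/spoke_of_sample")
    rhdf5::h5write(as.integer(s$time_of_sample), path,
                   "sampling/time_of_sample")
    rhdf5::h5write(s$spoke_angle_deg, path, "sampling/spoke_angle_deg")
    rhdf5::h5write(as.integer(c(s$n_timepoints, s$samples_per_spoke,
                                s$matrix_size)), path, "sampling/shape")
  } else {
    m <- ds$sampling$masks
    storage.mode(m) <- "integer"
    rhdf5::h5write(m, path, "sampling/mask")
  }
  if (!is.null(ds$sequence)) {
    sq <- ds$sequence
    rhdf5::h5createGroup(path, "sequence")
    rhdf5::h5write(sq$fa_deg, path, "sequence/fa_deg")
    rhdf5::h5write(sq$rf_phase_deg, path, "sequence/rf_phase_deg")
    rhdf5::h5write(sq$tr_ms, path, "sequence/tr_ms")
    rhdf5::h5write(sq$te_ms, path, "sequence/te_ms")
    rhdf5::h5write(as.integer(sq$invert), path, "sequence/inversion")
  }
  if (!is.null(ds$truth)) {
    rhdf5::h5createGroup(path, "truth")
    if (!is.null(ds$truth$t1_ms)) {
      rhdf5::h5write(ds$truth$t1_ms, path, "truth/t1")
      rhdf5::h5write(ds$truth$t2_ms, path, "truth/t2")
      lab <- ds$truth$label; storage.mode(lab) <- "integer"
      rhdf5::h5write(lab, path, "truth/label")
      h5_write_complex(ds$truth$m0, path, "truth/m0")
    }
    if (!is.null(ds$truth$images))
      h5_write_complex(ds$truth$images, path, "truth/images")
  }
  rhdf5::h5createGroup(path, "meta")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "meta")
  for (nm in names(ds$meta)) {
    v <- ds$meta[[nm]]
    if (!is.null(v)) rhdf5::h5writeAttribute(v, gid, nm)
  }
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls_df <- rhdf5::h5ls(path)
  entries <- paste(sub("^/$", "", ls_df$group), ls_df$name, sep = "/")
  need <- c("/kspace", "/sens", "/sampling")
  for (g in need) {
    if (!any(startsWith(entries, g)))
      stop("malformed container: missing group ", g, call. = FALSE)
  }
  kspace <- h5_read_complex(path, "kspace")
  sens <- h5_read_complex(path, "sens")
  meta <- rhdf5::h5readAttributes(path, "meta")
  meta <- lapply(meta, function(v) if (length(v) == 1) as.vector(v) else v)
  N <- dim(sens)[1]
  if ("/sampling/traj" %in% entries) {
    shape <- rhdf5::h5read(path, "sampling/shape")
    sampling <- structure(list(
      coords = rhdf5::h5read(path, "sampling/traj"),
      spoke_of_sample = as.integer(rhdf5::h5read(path,
                                                 "sampling/spoke_of_sample")),
      time_of_sample = as.integer(rhdf5::h5read(path,
                                                "sampling/time_of_sample")),
      spoke_angle_deg = as.vector(rhdf5::h5read(path,
                                                "sampling/spoke_angle_deg")),
      n_timepoints = as.integer(shape[1]), samples_per_spoke =
        as.integer(shape[2]), matrix_size = as.integer(shape[3]),
      type = "radial"), class = "radial_sampling")
    if (nrow(sampling$coords) != dim(kspace)[1])
      stop("dimension mismatch: trajectory rows vs k-space samples",
           call. = FALSE)
  } else if ("/sampling/mask" %in% entries) {
    m <- rhdf5::h5read(path, "sampling/mask")
    sampling <- structure(list(masks = m, accel = 1 / apply(m, 3, mean),
                               type = "cartesian"),
                          class = "cartesian_sampling")
    if (!all(dim(m)[1:2] == dim(sens)[1:2]))
      stop("dimension mismatch: mask grid vs sensitivity grid",
           call. = FALSE)
  } else {
    stop("malformed container: /sampling holds neither mask nor traj",
         call. = FALSE)
  }
  if (all(Mod(sens) == 0))
    stop("sensitivities are zero everywhere", call. = FALSE)
  sequence <- NULL
  if (any(startsWith(entries, "/sequence"))) {
    sequence <- sequence_params(
      fa_deg = as.vector(rhdf5::h5read(path, "sequence/fa_deg")),
      tr_ms = as.vector(rhdf5::h5read(path, "sequence/tr_ms")),
      te_ms = as.vector(rhdf5::h5read(path, "sequence/te_ms")),
      invert = as.vector(rhdf5::h5read(path, "sequence/inversion")) != 0,
      rf_phase_deg = as.vector(rhdf5::h5read(path, "sequence/rf_phase_deg")))
  }
  truth <- NULL
  if (any(startsWith(entries, "/truth"))) {
    truth <- list()
    if ("/truth/t1" %in% entries) {
      truth$t1_ms <- rhdf5::h5read(path, "truth/t1")
      truth$t2_ms <- rhdf5::h5read(path, "truth/t2")
      truth$label <- rhdf5::h5read(path, "truth/label")
      truth$m0 <- h5_read_complex(path, "truth/m0")
    }
    if ("/truth/images" %in% entries)
      truth$images <- h5_read_complex(path, "truth/images")
  }
  structure(list(kspace = kspace, sampling = sampling, sens = sens,
                 sequence = sequence, truth = truth, meta = meta),
            class = "hdprost_dataset")
}

#' Save / load quantitative maps as NIfTI
#'
#' Writes `<prefix>_t1.nii.gz`, `<prefix>_t2.nii.gz` (ms) and
#' `<prefix>_m0.nii.gz` (proton density magnitude).  Voxels outside the mask
#' are written as zero; non-finite values inside the mask are an error.
#'
#' @param maps a `parameter_maps` (see [match_fingerprints()]).
#' @param prefix output path prefix.
#' @return character vector of the three paths, invisibly.
#' @export
save_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "parameter_maps"))
  mask <- maps$mask & !maps$zero_signal
  clean <- function(v) {
    v[!mask] <- 0
    if (any(!is.finite(v[mask])))
      stop("non-finite map values inside the mask", call. = FALSE)
    v
  }
  vols <- list(t1 = clean(maps$t1_ms), t2 = clean(maps$t2_ms),
               m0 = clean(Mod(maps$m0)))
  paths <- paste0(prefix, "_", names(vols), ".nii.gz")
  for (i in seq_along(vols)) RNifti::writeNifti(RNifti::asNifti(vols[[i]]),
                                                paths[i])
  invisible(paths)
}

#' @rdname save_maps
#' @export
load_maps <- function(prefix) {
  rd <- function(sfx) {
    a <- RNifti::readNifti(paste0(prefix, "_", sfx, ".nii.gz"))
    array(as.numeric(a), dim(a))
  }
  list(t1_ms = rd("t1"), t2_ms = rd("t2"), m0_mag = rd("m0"))
}

#' Persist an MRF dictionary
#'
#' HDF5 layout: `/dict/atoms_{real,imag}`, `/dict/norms`,
#' `/dict/{t1_grid,t2_grid}`, optional `/dict/basis_{real,imag}` and
#' `/dict/atoms_compressed_{real,imag}`, and the sequence under `/sequence`.
#'
#' @param dict an `mrf_dictionary`.
#' @param path HDF5 file path.
#' @return `path`, invisibly.
#' @export
save_dictionary <- function(dict, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "dict")
  rhdf5::h5write(Re(dict$atoms), path, "dict/atoms_real")
  rhdf5::h5write(Im(dict$atoms), path, "dict/atoms_imag")
  rhdf5::h5write(dict$norms, path, "dict/norms")
  rhdf5::h5write(dict$t1_grid_ms, path, "dict/t1_grid")
  rhdf5::h5write(dict$t2_grid_ms, path, "dict/t2_grid")
  if (!is.null(dict$basis)) {
    rhdf5::h5write(Re(dict$basis$Ur), path, "dict/basis_real")
    rhdf5::h5write(Im(dict$basis$Ur), path, "dict/basis_imag")
    rhdf5::h5write(Re(dict$atoms_compressed), path,
                   "dict/atoms_compressed_real")
    rhdf5::h5write(Im(dict$atoms_compressed), path,
                   "dict/atoms_compressed_imag")
  }
  sq <- dict$seq
  rhdf5::h5createGroup(path, "sequence")
  rhdf5::h5write(sq$fa_deg, path, "sequence/fa_deg")
  rhdf5::h5write(sq$rf_phase_deg, path, "sequence/rf_phase_deg")
  rhdf5::h5write(sq$tr_ms, path, "sequence/tr_ms")
  rhdf5::h5write(sq$te_ms, path, "sequence/te_ms")
  rhdf5::h5write(as.integer(sq$invert), path, "sequence/inversion")
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls_df <- rhdf5::h5ls(path)
  entries <- paste(sub("^/$", "", ls_df$group), ls_df$name, sep = "/")
  atoms <- array(complex(real = rhdf5::h5read(path, "dict/atoms_real"),
                         imaginary = rhdf5::h5read(path, "dict/atoms_imag")),
                 dim = dim(rhdf5::h5read(path, "dict/atoms_real")))
  t1g <- as.vector(rhdf5::h5read(path, "dict/t1_grid"))
  t2g <- as.vector(rhdf5::h5read(path, "dict/t2_grid"))
  grid <- expand.grid(t1 = t1g, t2 = t2g, KEEP.OUT.ATTRS = FALSE)
  seq <- sequence_params(
    fa_deg = as.vector(rhdf5::h5read(path, "sequence/fa_deg")),
    tr_ms = as.vector(rhdf5::h5read(path, "sequence/tr_ms")),
    te_ms = as.vector(rhdf5::h5read(path, "sequence/te_ms")),
    invert = as.vector(rhdf5::h5read(path, "sequence/inversion")) != 0,
    rf_phase_deg = as.vector(rhdf5::h5read(path, "sequence/rf_phase_deg")))
  dict <- structure(list(
    atoms = atoms, norms = as.vector(rhdf5::h5read(path, "dict/norms")),
    t1_ms = grid$t1, t2_ms = grid$t2, t1_grid_ms = t1g, t2_grid_ms = t2g,
    seq = seq, basis = NULL, atoms_compressed = NULL),
    class = "mrf_dictionary")
  if ("/dict/basis_real" %in% entries) {
    br <- rhdf5::h5read(path, "dict/basis_real")
    Ur <- array(complex(real = br,
                        imaginary = rhdf5::h5read(path, "dict/basis_imag")),
                dim = dim(br))
    acr <- rhdf5::h5read(path, "dict/atoms_compressed_real")
    dict$basis <- list(Ur = Ur, r = ncol(Ur), sv = NULL)
    dict$atoms_compressed <- array(
      complex(real = acr,
              imaginary = rhdf5::h5read(path, "dict/atoms_compressed_imag")),
      dim = dim(acr))
  }
  dict
}

#' Save / load a complex image stack
#'
#' Small HDF5 helper (`/images/{real,imag}`) used by the command-line
#' pipeline to hand reconstructed subspace images to the matching stage.
#'
#' @param images complex array.
#' @param path HDF5 file path.
#' @export
save_images <- function(images, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5_write_complex(as.array(images), path, "images")
  invisible(path)
}

#' @rdname save_images
#' @export
load_images <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5_read_complex(path, "images")
}
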