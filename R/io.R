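# Manifest/PNG/config readers and writers. The CSV manifest (columns
# path,label,client,country,split) is the single source of dataset truth;
# labels are stored as class-name strings and mapped to ids through the
# four-plane vocabulary.

#' Write a dataset as PNG files plus a CSV manifest
#'
#' @param ds a `plane_dataset`.
#' @param dir output directory (created if needed); images go into
#'   per-client subdirectories.
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(ds)
  paths <- character(n)
  for (i in seq_len(n)) {
    sub <- file.path(dir, ds$client[i])
    dir.create(sub, showWarnings = FALSE)
    paths[i] <- file.path(ds$client[i], sprintf("img_%05d.png", i))
    png::writePNG(ds$images[[i]], file.path(dir, paths[i]))
  }
  manifest <- data.frame(path = paths,
                         label = CLASS_NAMES[ds$labels + 1],
                         client = ds$client, country = ds$country,
                         split = ds$split)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read and validate a dataset manifest
#'
#' @param path manifest CSV path; image paths are resolved relative to its
#'   directory.
#' @param check_paths verify that every image file exists.
#' @return data.frame with the manifest columns plus `label_id` and
#'   absolute `abs_path`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("path", "label", "client", "country", "split")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop("manifest ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!m$label %in% CLASS_NAMES)
  if (length(bad)) {
    stop("unknown label '", m$label[bad[1]], "' at ", path, " line ",
         bad[1] + 1)
  }
  bad <- which(!m$split %in% c("train", "val", "test"))
  if (length(bad)) {
    stop("invalid split '", m$split[bad[1]], "' at ", path, " line ",
         bad[1] + 1)
  }
  m$label_id <- match(m$label, CLASS_NAMES) - 1L
  m$abs_path <- file.path(dirname(path), m$path)
  if (check_paths) {
    bad <- which(!file.exists(m$abs_path))
    if (length(bad)) {
      stop("image file not found: ", m$path[bad[1]], " (", path, " line ",
           bad[1] + 1, ")")
    }
  }
  m
}

#' Load a dataset from a manifest
#'
#' @param manifest path to a manifest CSV, or a data.frame from
#'   [read_manifest()].
#' @return a `plane_dataset`.
#' @export
load_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  images <- lapply(manifest$abs_path, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  new_plane_dataset(images, manifest$label_id, manifest$client,
                    manifest$country, manifest$split)
}

#' Default run configuration
#'
#' All study defaults in one nested list: temperature 0.5, k = 50,
#' th = 40, 5 rounds x 20 epochs, learning rate 0.05 annealed to 1e-5,
#' batch size 16, mix-up alpha 0.5, 8 views.
#'
#' @return nested configuration list (class `run_config`).
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1,
    mode = "proposed",
    out_dir = "fedproto_out",
    contrastive = list(tau = 0.5, batch_pairs = 32, embedding_dim = 64,
                       projection_dim = 32, epochs = 10, lr = 0.05,
                       momentum = 0.9),
    denoise = list(k = 50, th = 40, mode = "consensus_keep"),
    views = list(n_views = 8),
    augmentation = list(hflip_prob = 0.5, max_rotation_deg = 15,
                        max_shift_px = 12, brightness_range = c(0.7, 1.3),
                        contrast_range = c(0.7, 1.3)),
    federation = list(rounds = 5, local_epochs = 20, batch_size = 16,
                      lr_init = 0.05, lr_min = 1e-5, momentum = 0.9,
                      mixup_alpha = 0.5),
    noise = list(rate_repr = 0.2, rate_norepr = 0.2,
                 model = "symmetric_exclusive")
  ), class = "run_config")
}

validate_config <- function(cfg, ref = default_run_config(), path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown)) {
    stop("unknown config key: ", path, unknown[1])
  }
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      if (!is.list(cfg[[nm]])) stop("config field ", path, nm,
                                    " must be a mapping")
      validate_config(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected with the offending field path; omitted keys
#' fall back to [default_run_config()] values, and basic invariants
#' (positive temperature, threshold in `(0, 100]`, learning-rate ordering)
#' are checked.
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  full <- utils::modifyList(default_run_config(), cfg)
  with(full, {
    stopifnot(contrastive$tau > 0,
              denoise$th > 0, denoise$th <= 100, denoise$k >= 1,
              federation$rounds >= 1,
              federation$lr_init > federation$lr_min,
              federation$lr_min > 0,
              noise$rate_repr >= 0, noise$rate_repr <= 1,
              noise$rate_norepr >= 0, noise$rate_norepr <= 1)
  })
  class(full) <- "run_config"
  full
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(unclass(cfg), NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}

#' Save a model checkpoint
#'
#' @param params named parameter list (or an `encoder`).
#' @param path output file.
#' @param metadata named list stored alongside (architecture id, seed,
#'   stage, ...); a config hash is added when `config` is supplied.
#' @param config optional configuration to hash into the metadata.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(params, path, metadata = list(), config = NULL) {
  if (inherits(params, "encoder")) {
    metadata$arch <- params$arch
    metadata$embedding_dim <- params$embedding_dim
    params <- params$params
  }
  if (!is.null(config)) metadata$config_hash <- config_hash(config)
  saveRDS(list(params = params, metadata = metadata), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path checkpoint file from [save_checkpoint()].
#' @return list with `params` and `metadata`.
#' @export
load_checkpoint <- function(path) readRDS(path)
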