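# Model persistence. A saved model is a directory holding a JSON manifest
# (format version, stage parameters, feature-name lists, content hashes)
# plus the serialized estimator state. Hashes are MD5 over the serialized
# objects: they bind a manifest to its estimator files for integrity
# checking, not for security.

BUNDLE_FORMAT_VERSION <- 1L

hash_object <- function(obj) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(obj, f, compress = FALSE, version = 2L)
  unname(tools::md5sum(f))
}

model_manifest_entry <- function(model) {
  list(
    stage = model$stage,
    params = model$params[setdiff(names(model$params), "extra")],
    extra = model$params$extra,
    feature_names = model$feature_names,
    threshold = model$threshold,
    metadata = model$metadata
  )
}

#' Save a trained model or two-stage bundle to disk
#'
#' Writes a directory with `manifest.json` plus one `.rds` per stage. The
#' manifest records the format version, all training parameters, the exact
#' ordered feature-name list of each stage and an MD5 hash of every
#' estimator file, so tampering is detected at load time.
#'
#' @param bundle A `cpp_model` or `cpp_two_stage`.
#' @param path Directory to create (must not already contain a manifest).
#' @return `path`, invisibly.
#' @export
save_model <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (inherits(bundle, "cpp_model")) {
    stages <- list(model = bundle)
    kind <- "single"
  } else if (inherits(bundle, "cpp_two_stage")) {
    stages <- list(stage1 = bundle$stage1, stage2 = bundle$stage2)
    kind <- "two_stage"
  } else {
    cpp_stop("`bundle` must be a cpp_model or cpp_two_stage", "config")
  }
  files <- list()
  for (nm in names(stages)) {
    f <- file.path(path, paste0(nm, ".rds"))
    saveRDS(stages[[nm]], f)
    files[[nm]] <- list(file = basename(f), md5 = unname(tools::md5sum(f)))
  }
  if (kind == "two_stage") {
    f <- file.path(path, "selection.rds")
    saveRDS(list(selection = bundle$selection, config = bundle$config,
                 atomic_config = bundle$atomic_config), f)
    files[["selection"]] <- list(file = basename(f),
                                 md5 = unname(tools::md5sum(f)))
  }
  manifest <- list(
    format_version = BUNDLE_FORMAT_VERSION,
    kind = kind,
    stages = lapply(stages, model_manifest_entry),
    files = files
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a model bundle saved by [save_model()]
#'
#' Verifies the manifest format version and the MD5 hash of every
#' estimator file, and cross-checks the manifest's feature-name lists
#' against the deserialized models.
#'
#' @param path Bundle directory.
#' @return The `cpp_model` or `cpp_two_stage` that was saved.
#' @export
load_model <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) cpp_stop(sprintf("no manifest at %s", path), "io")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  if (manifest$format_version > BUNDLE_FORMAT_VERSION) {
    cpp_stop(sprintf("bundle format version %s is newer than supported (%d)",
                     manifest$format_version, BUNDLE_FORMAT_VERSION),
             "version_mismatch")
  }
  objs <- list()
  for (nm in names(manifest$files)) {
    entry <- manifest$files[[nm]]
    f <- file.path(path, entry$file)
    if (!file.exists(f) || !identical(unname(tools::md5sum(f)), entry$md5)) {
      cpp_stop(sprintf("hash mismatch for %s", entry$file), "hash_mismatch")
    }
    objs[[nm]] <- readRDS(f)
  }
  for (nm in names(manifest$stages)) {
    declared <- unlist(manifest$stages[[nm]]$feature_names)
    if (!identical(declared, objs[[nm]]$feature_names)) {
      cpp_stop(sprintf("manifest feature names disagree with estimator for %s",
                       nm), "hash_mismatch")
    }
  }
  if (manifest$kind == "single") return(objs$model)
  structure(list(stage1 = objs$stage1, stage2 = objs$stage2,
                 selection = objs$selection$selection,
                 config = objs$selection$config,
                 atomic_config = objs$selection$atomic_config),
            class = "cpp_two_stage")
}
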