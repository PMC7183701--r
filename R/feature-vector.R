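# The canonical 146-feature panel: registry, assembly, aliases, IO.

.fos_names <- c("fos_mean", "fos_variance", "fos_skewness",
                "fos_kurtosis", "fos_energy", "fos_entropy")
.glcm_names <- c("glcm_energy", "glcm_contrast", "glcm_correlation",
                 "glcm_homogeneity", "glcm_entropy", "glcm_dissimilarity")
.glrlm_names <- c("glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_rp",
                  "glrlm_rln", "glrlm_lglre", "glrlm_hglre")
.lbp_names <- c(paste0("lbp_u", 0:8), "lbp_nonuniform")
.shape_names <- c("shape_area", "shape_perimeter", "shape_major_axis",
                  "shape_minor_axis", "shape_eccentricity",
                  "shape_solidity", "shape_extent",
                  "shape_equiv_diameter", "shape_circularity")

#' The canonical feature registry
#'
#' Fixed, versioned ordering of the 146-feature panel: F1-F6 first-order,
#' F7-F12 GLCM (direction-averaged), F13-F19 GLRLM, F20-F29 LBP histogram,
#' F30 fractal dimension, F31-F118 wavelet domain (LL, LH, HL, HH x 22),
#' F119-F137 gradient domain, F138-F146 shape. Within-block orders place
#' GLCM contrast at F8, GLRLM run percentage at F16, gradient GLCM
#' contrast at F126 and gradient GLCM entropy at F129.
#'
#' @return Data frame with columns `index`, `name`, `domain`, `family`.
#' @export
feature_registry <- function() {
  if (!is.null(.registry_cache$reg)) return(.registry_cache$reg)
  rows <- list(
    data.frame(name = .fos_names, domain = "intensity", family = "fos"),
    data.frame(name = .glcm_names, domain = "intensity", family = "glcm"),
    data.frame(name = .glrlm_names, domain = "intensity", family = "glrlm"),
    data.frame(name = .lbp_names, domain = "intensity", family = "lbp"),
    data.frame(name = "fractal_dimension", domain = "intensity",
               family = "fractal"))
  for (sb in c("LL", "LH", "HL", "HH")) {
    nm <- paste0("wav_", sb, "_",
                 c(.fos_names, .glcm_names, .glrlm_names,
                   "rel_energy", "log_energy", "mean_abs"))
    fam <- c(rep("fos", 6), rep("glcm", 6), rep("glrlm", 7),
             rep("subband_summary", 3))
    rows[[length(rows) + 1]] <-
      data.frame(name = nm, domain = paste0("wavelet_", sb), family = fam)
  }
  rows[[length(rows) + 1]] <- data.frame(
    name = paste0("grad_", c(.fos_names, .glcm_names, .glrlm_names)),
    domain = "gradient",
    family = c(rep("fos", 6), rep("glcm", 6), rep("glrlm", 7)))
  rows[[length(rows) + 1]] <- data.frame(
    name = .shape_names, domain = "shape", family = "shape")
  reg <- do.call(rbind, rows)
  reg <- data.frame(index = seq_len(nrow(reg)), reg,
                    stringsAsFactors = FALSE)
  stopifnot(nrow(reg) == 146, !anyDuplicated(reg$name))
  .registry_cache$reg <- reg
  reg
}

.registry_cache <- new.env(parent = emptyenv())

# Published aliases for the five named panel members.
.feature_aliases <- c(
  "Contrast" = "glcm_contrast",
  "Run percentage" = "glrlm_rp",
  "Low gray level run emphasis of approximate wavelet image" =
    "wav_LL_glrlm_lglre",
  "Contrast of gradient image" = "grad_glcm_contrast",
  "Entropy of the gradient image" = "grad_glcm_entropy")

#' Look up a feature index by canonical name or published alias
#'
#' @param name Canonical registry name (e.g. `"glcm_contrast"`) or a
#'   published alias (e.g. `"Contrast"`, `"Run percentage"`).
#' @return Integer index into the 146-feature vector.
#' @export
feature_index <- function(name) {
  reg <- feature_registry()
  resolved <- ifelse(name %in% names(.feature_aliases),
                     .feature_aliases[name], name)
  idx <- match(resolved, reg$name)
  if (anyNA(idx)) stop("unknown feature name: ",
                       paste(name[is.na(idx)], collapse = ", "))
  stats::setNames(as.integer(idx), name)
}

#' Assemble the full 146-feature vector for one case
#'
#' Runs every extractor on the case's image/mask in the canonical order.
#' Errors from a component extractor are re-signalled with the failing
#' feature family named.
#'
#' @param case A `case_record` (or list with `image`, `mask`, `spacing`).
#' @param n_levels Quantization levels (default 8).
#' @return Named numeric vector of length 146.
#' @export
assemble_feature_vector <- function(case, n_levels = 8) {
  run <- function(family, expr) {
    tryCatch(expr, error = function(e)
      stop("feature family '", family, "' failed for case ",
           case$case_id %||% "?", ": ", conditionMessage(e), call. = FALSE))
  }
  img <- case$image
  mask <- case$mask > 0.5
  spacing <- if (!is.null(case$spacing)) case$spacing[1] else 1
  roi <- run("quantization", normalize_quantize(img, mask, n_levels))
  out <- c(
    run("first-order", first_order_stats(roi)),
    run("glcm", glcm_features(roi)),
    run("glrlm", glrlm_features(roi)),
    run("lbp", lbp_features(img, mask)),
    fractal_dimension = run("fractal",
                            suppressWarnings(fractal_dimension(img, mask))),
    run("wavelet", wavelet_features(img, mask, n_levels)),
    run("gradient", gradient_features(img, mask, n_levels)),
    run("shape", shape_features(mask, spacing)))
  reg <- feature_registry()
  stopifnot(identical(names(out), reg$name))
  out
}

#' Extract the feature table for a whole cohort
#'
#' @param cohort List of `case_record`s.
#' @param n_levels Quantization levels (default 8).
#' @return Data frame: `case_id`, `label`, then the 146 feature columns.
#' @export
extract_features <- function(cohort, n_levels = 8) {
  mat <- t(vapply(cohort, assemble_feature_vector, numeric(146),
                  n_levels = n_levels))
  out <- data.frame(
    case_id = vapply(cohort, `[[`, character(1), "case_id"),
    label = vapply(cohort, `[[`, integer(1), "label"),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mat))
}

#' Write / read a feature table as CSV
#'
#' @param features Data frame from [extract_features()].
#' @param path CSV path.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Export the feature registry as JSON
#'
#' @param path Output path.
#' @export
write_feature_registry <- function(path) {
  reg <- feature_registry()
  doc <- list(version = as.character(utils::packageVersion("lnradiomics")),
              n_features = nrow(reg),
              aliases = as.list(.feature_aliases),
              features = reg)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
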