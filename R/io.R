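#' Read a square symmetric matrix from TSV
#'
#' Expects a tab-separated file whose first row and first column carry
#' matching node names. Asymmetries up to 1e-10 are silently averaged
#' out; larger ones are symmetrised with a warning. A nonzero diagonal is
#' zeroed with a warning.
#'
#' @param path file path.
#' @return Named symmetric matrix with zero diagonal.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop("matrix in ", path, " is not square (", nrow(m), " x ", ncol(m), ")")
  if (!identical(rownames(m), colnames(m)))
    stop("row/column name mismatch in ", path)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("NaN/NA at row '", rownames(m)[bad[1]], "', column '",
         colnames(m)[bad[2]], "' in ", path)
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-10)
    warning("asymmetry up to ", signif(asym, 3), " symmetrised by averaging")
  m <- (m + t(m)) / 2
  if (any(diag(m) != 0)) {
    warning("nonzero diagonal zeroed")
    diag(m) <- 0
  }
  m
}

#' Write a square matrix as TSV (full precision)
#'
#' @param m matrix with dimnames (defaults are generated if absent).
#' @param path file path.
#' @export
write_matrix <- function(m, path) {
  if (is.null(rownames(m)))
    dimnames(m) <- rep(list(sprintf("node_%03d", seq_len(nrow(m)))), 2)
  lines <- c(paste(c("", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a tractogram as JSON-lines
#'
#' One streamline per line: voxel indices (1-based, k x 3), per-voxel
#' segment lengths (mm), tangents, endpoint node pair and total length.
#' A header line carries the grid shape and node map.
#'
#' @param tractogram a `tractogram`.
#' @param path file path.
#' @export
write_tractogram <- function(tractogram, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(grid_shape = tractogram$grid_shape,
                                   node_map = tractogram$node_map),
                              auto_unbox = FALSE), con)
  for (s in tractogram$streamlines)
    writeLines(jsonlite::toJSON(list(
      voxels = s$voxels, seg_lengths = s$seg_lengths,
      tangents = s$tangents, endpoints = s$endpoints,
      length = s$length), auto_unbox = FALSE, digits = NA), con)
  invisible(path)
}

#' @rdname write_tractogram
#' @return `read_tractogram`: the `tractogram` object.
#' @export
read_tractogram <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  streamlines <- lapply(lines[-1], function(l) {
    s <- jsonlite::fromJSON(l)
    list(voxels = matrix(as.integer(s$voxels), ncol = 3),
         seg_lengths = as.numeric(s$seg_lengths),
         tangents = matrix(as.numeric(s$tangents), ncol = 3),
         endpoints = as.numeric(s$endpoints),
         length = as.numeric(s$length))
  })
  structure(list(grid_shape = as.integer(hdr$grid_shape),
                 node_map = as.integer(hdr$node_map),
                 streamlines = streamlines), class = "tractogram")
}

#' Write / read FSL-style gradient tables
#'
#' `bvals`: one space-separated row of b-values. `bvecs`: three rows
#' (x, y, z components).
#'
#' @param gradients a [gradient_table()].
#' @param bvals_path,bvecs_path output paths.
#' @export
write_gradients <- function(gradients, bvals_path, bvecs_path) {
  writeLines(paste(sprintf("%.17g", gradients$b_values), collapse = " "),
             bvals_path)
  writeLines(apply(t(gradients$directions), 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), bvecs_path)
  invisible(NULL)
}

#' @rdname write_gradients
#' @return `read_gradients`: a `gradient_table`.
#' @export
read_gradients <- function(bvals_path, bvecs_path) {
  bv <- scan(bvals_path, quiet = TRUE)
  vecs <- t(as.matrix(utils::read.table(bvecs_path)))
  gradient_table(bv, vecs)
}

#' Load the packaged AAL-116 node table
#'
#' The 116-region automated anatomical labelling parcellation with
#' cerebellar-hemisphere and vermis flags, as consumed by
#' [merge_cerebellar()].
#'
#' @return data.frame: `node_id`, `name`, `is_cerebellar_hemispheric`,
#'   `is_vermis`, `homologue_id`.
#' @export
aal116_nodes <- function() {
  path <- system.file("extdata", "aal116_nodes.tsv", package = "quantconn")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$is_cerebellar_hemispheric <- as.logical(df$is_cerebellar_hemispheric)
  df$is_vermis <- as.logical(df$is_vermis)
  df
}

#' Write a synthetic cohort to a directory
#'
#' One TSV matrix per subject per modality, a covariates CSV and a JSON
#' manifest holding the generating configuration.
#'
#' @param cohort a `cohort` from [gen_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cv <- cohort$covariates
  for (s in seq_len(nrow(cv))) {
    if (!is.null(cohort$struct))
      write_matrix(cohort$struct[[s]],
                   file.path(dir, paste0(cv$subject_id[s], "_struct.tsv")))
    if (!is.null(cohort$func))
      write_matrix(cohort$func[[s]],
                   file.path(dir, paste0(cv$subject_id[s], "_func.tsv")))
  }
  utils::write.csv(cv, file.path(dir, "covariates.csv"), row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(
    list(config = cfg,
         ground_truth = list(
           subnet_nodes = cohort$ground_truth$subnet_nodes,
           subnet_edges = cohort$ground_truth$subnet_edges)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
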