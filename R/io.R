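## Readers and writers: TSV/CSV matrices, annotations, ontologies, splits,
## latent matrices, h5ad ingestion, PNG / text images.

#' Read a sample-by-feature matrix from TSV/CSV
#'
#' First column holds sample ids, the header row holds feature ids; the
#' delimiter is inferred from the extension (`.csv` = comma, otherwise tab).
#'
#' @param path input file.
#' @param name modality name (defaults to the file stem).
#' @param kind modality kind.
#' @return a [modality_block()].
#' @export
read_matrix <- function(path, name = NULL,
                        kind = c("numeric", "categorical", "image")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicated sample_ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  modality_block(name, m, kind = kind)
}

#' Write a matrix (or modality block) as TSV with a sample_id column
#' @export
write_matrix <- function(x, path) {
  m <- if (inherits(x, "modality_block")) x$matrix else as.matrix(x)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation table (TSV keyed by sample_id)
#' @param path TSV with a `sample_id` column.
#' @param tasks optional data.frame(column, task).
#' @export
read_annotation <- function(path, tasks = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("annotation file needs a sample_id column")
  annotation_table(df, task_specs = tasks)
}

#' Read an ontology from two-column edge TSVs
#' @param lvl1_path feature_id, term_id edges.
#' @param lvl2_path optional term_id, super_term_id edges.
#' @export
read_ontology <- function(lvl1_path, lvl2_path = NULL) {
  e1 <- utils::read.table(lvl1_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  e2 <- if (!is.null(lvl2_path)) {
    utils::read.table(lvl2_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  ontology_map(e1, e2)
}

#' Write / read a split assignment as two-column TSV
#' @export
write_split <- function(split, path) {
  utils::write.table(data.frame(sample_id = names(split),
                                split = as.character(split)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- factor(df$split, levels = c("train", "valid", "test"))
  names(out) <- df$sample_id
  class(out) <- c("split_assignment", "factor")
  out
}

#' Ingest an AnnData h5ad file as one modality block plus annotations
#'
#' Reads the main matrix `X` (dense or CSR/CSC sparse, densified under a size
#' guard), `obs` columns as annotations and `var` names as feature ids.
#' Requires the `rhdf5` package.
#'
#' @param path h5ad file.
#' @param name modality name.
#' @param max_cells maximum densified size (rows x columns).
#' @return list with `block` ([modality_block()]) and `annotations`.
#' @export
read_h5ad <- function(path, name = "h5ad", max_cells = 5e7) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("read_h5ad requires the 'rhdf5' package")
  }
  if (!file.exists(path)) stop("h5ad file not found: ", path)
  h5 <- rhdf5::h5ls(path)
  read_index <- function(group) {
    attrs <- rhdf5::h5readAttributes(path, group)
    idx_name <- if (!is.null(attrs[["_index"]])) attrs[["_index"]] else "_index"
    as.character(rhdf5::h5read(path, paste0(group, "/", idx_name)))
  }
  obs_ids <- read_index("obs")
  var_ids <- read_index("var")
  n <- length(obs_ids)
  p <- length(var_ids)
  if (as.double(n) * p > max_cells) {
    stop("h5ad matrix of ", n, " x ", p, " exceeds the densification guard; ",
         "pre-filter features before ingestion")
  }
  x_entries <- h5$name[h5$group == "/X"]
  if (length(x_entries) && all(c("data", "indices", "indptr") %in% x_entries)) {
    at <- rhdf5::h5readAttributes(path, "X")
    enc <- if (!is.null(at[["encoding-type"]])) at[["encoding-type"]] else "csr_matrix"
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    m <- matrix(0, n, p)
    if (grepl("csr", enc)) {
      for (i in seq_len(n)) {
        jj <- if (indptr[i + 1] > indptr[i]) (indptr[i] + 1):indptr[i + 1] else integer()
        m[i, indices[jj] + 1L] <- data[jj]
      }
    } else {
      for (j in seq_len(p)) {
        ii <- if (indptr[j + 1] > indptr[j]) (indptr[j] + 1):indptr[j + 1] else integer()
        m[indices[ii] + 1L, j] <- data[ii]
      }
    }
  } else {
    m <- rhdf5::h5read(path, "X")
    ## h5py writes row-major; HDF5 dims arrive as (var, obs) in R
    if (nrow(m) == p && ncol(m) == n) m <- t(m) else m <- as.matrix(m)
  }
  dimnames(m) <- list(obs_ids, var_ids)
  ## obs columns: plain datasets or categorical groups (codes + categories)
  obs_items <- h5[h5$group == "/obs", , drop = FALSE]
  ann <- data.frame(row.names = obs_ids)
  for (nm in setdiff(obs_items$name, c("_index", "index"))) {
    obj <- paste0("obs/", nm)
    val <- tryCatch({
      sub <- h5[h5$group == paste0("/obs/", nm), , drop = FALSE]
      if (nrow(sub) && all(c("categories", "codes") %in% sub$name)) {
        cats <- as.character(rhdf5::h5read(path, paste0(obj, "/categories")))
        codes <- as.integer(rhdf5::h5read(path, paste0(obj, "/codes")))
        ifelse(codes >= 0, cats[codes + 1L], NA)
      } else {
        v <- rhdf5::h5read(path, obj)
        if (is.array(v)) v <- as.vector(v)
        v
      }
    }, error = function(e) NULL)
    if (!is.null(val) && length(val) == n) ann[[nm]] <- val
  }
  if (requireNamespace("rhdf5", quietly = TRUE)) rhdf5::h5closeAll()
  list(block = modality_block(name, m, kind = "numeric"),
       annotations = annotation_table(ann))
}

#' Read one image file (PNG or plain-text matrix) into a [0,1] matrix
#'
#' PNG requires the `png` package; `.csv`/`.tsv`/`.txt` files hold a plain
#' numeric pixel matrix.
#' @param path image file.
#' @export
read_image_file <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("PNG reading requires the 'png' package")
    }
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    return(img)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  as.matrix(utils::read.table(path, header = FALSE, sep = sep))
}

#' Write a grayscale [0,1] matrix as PNG (or text matrix fallback)
#' @keywords internal
write_image_file <- function(img, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE) &&
      requireNamespace("png", quietly = TRUE)) {
    png::writePNG(pmin(pmax(img, 0), 1), path)
  } else {
    path <- sub("\\.png$", ".tsv", path)
    utils::write.table(img, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Load an image modality from a manifest TSV
#'
#' The manifest has columns sample_id, path, channels, height, width; paths
#' are resolved relative to `dir`. Images are preprocessed with
#' [image_preprocess()] to `target_side` and flattened row-wise into a
#' modality block.
#'
#' @param manifest_path manifest TSV.
#' @param dir base directory for relative image paths.
#' @param target_side output side (divisible by 32).
#' @export
load_image_block <- function(manifest_path, dir = dirname(manifest_path),
                             target_side = NULL) {
  mf <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  imgs <- lapply(mf$path, function(p) {
    full <- if (file.exists(p)) p else file.path(dir, p)
    image_preprocess(read_image_file(full), target_side = target_side)
  })
  side <- nrow(imgs[[1]])
  X <- t(vapply(imgs, function(im) as.vector(t(im)), numeric(side * side)))
  rownames(X) <- mf$sample_id
  colnames(X) <- sprintf("px%05d", seq_len(side * side))
  mf$height <- side
  mf$width <- side
  modality_block("images", X, kind = "image", image_manifest = mf)
}

#' Write a latent matrix as TSV with a sample_id index
#' @export
write_latent <- function(z, path) {
  if (is.null(colnames(z))) colnames(z) <- sprintf("L%02d", seq_len(ncol(z)))
  write_matrix(z, path)
}

#' @rdname write_latent
#' @export
read_latent <- function(path) {
  b <- read_matrix(path, name = "latent")
  b$matrix
}

#' Export visualization-ready latent summaries
#'
#' Writes a tidy ridge-line TSV (per class x latent dimension x histogram
#' bin) and, when a PNG device is available, a 2-D scatter colored by the
#' chosen annotation (direct for 2-D latents, UMAP-projected otherwise).
#'
#' @param z latent matrix with sample rownames.
#' @param annotations an [annotation_table()] covering the same samples.
#' @param color_by annotation column for coloring/grouping.
#' @param outdir output directory.
#' @param bins histogram bins for the ridge data.
#' @return (invisibly) the paths written.
#' @export
export_visualization <- function(z, annotations, color_by, outdir, bins = 30) {
  if (!color_by %in% names(annotations)) {
    stop("annotation column not found: ", color_by)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  z <- as.matrix(z)
  cls <- as.character(annotations[rownames(z), color_by])
  ## ridge-line data: per class and latent dim, histogram of intensities
  ridge <- list()
  for (d in seq_len(ncol(z))) {
    br <- seq(min(z[, d]), max(z[, d]), length.out = bins + 1)
    if (br[1] == br[length(br)]) br <- br[1] + c(-0.5, 0.5)
    for (cl in sort(unique(cls))) {
      h <- graphics::hist(z[cls == cl, d], breaks = br, plot = FALSE)
      ridge[[length(ridge) + 1L]] <- data.frame(
        class = cl, dim = colnames(z)[d] %||% paste0("L", d),
        bin_mid = h$mids, density = h$density)
    }
  }
  ridge_path <- file.path(outdir, "latent_ridge.tsv")
  utils::write.table(do.call(rbind, ridge), ridge_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- ridge_path
  ## 2-D scatter
  xy <- if (ncol(z) == 2) z else tryCatch(
    baseline_embeddings(z, 2, "umap"), error = function(e) NULL)
  if (!is.null(xy) && capabilities("png")) {
    sc_path <- file.path(outdir, "latent_scatter.png")
    grDevices::png(sc_path, width = 900, height = 800, res = 120)
    cols <- as.integer(factor(cls))
    graphics::plot(xy[, 1], xy[, 2], col = cols, pch = 19, cex = 0.6,
                   xlab = "dim 1", ylab = "dim 2",
                   main = paste("latent space by", color_by))
    graphics::legend("topright", legend = levels(factor(cls)),
                     col = seq_along(levels(factor(cls))), pch = 19, cex = 0.7)
    grDevices::dev.off()
    paths <- c(paths, sc_path)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
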