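# File interchange: multi-page 16-bit TIFF stacks with a JSON voxel-size
# sidecar, CSV flow-event tables, and TSV outputs for scores, objects and
# catalogs.

#' Write a stack as multi-page 16-bit TIFF with JSON sidecar
#'
#' One page per z-slice; intensities are rounded to integers (clipped to
#' 0..65535). Voxel size is stored in `<path>.json`.
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- pmin(pmax(round(stack$voxels), 0), 65535)
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(voxel_size_um = stack$voxel_size,
                            axes = c("z", "y", "x")),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack with JSON sidecar
#'
#' @param path TIFF path; voxel size is read from `<path>.json` unless given.
#' @param voxel_size optional `(dz, dy, dx)` um override.
#' @return an [image_stack].
#' @export
read_image_stack <- function(path, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(voxel_size)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) stop("no voxel size: sidecar ", sidecar, " missing")
    voxel_size <- as.numeric(jsonlite::read_json(sidecar,
                                                 simplifyVector = TRUE)$voxel_size_um)
  }
  arr <- array(0, c(length(pages), dim(pages[[1]])[1:2]))
  for (z in seq_along(pages)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    arr[z, , ] <- round(pg * 65535)
  }
  image_stack(arr, voxel_size)
}

#' Read / write flow-cytometry event tables as CSV
#'
#' Columns: `plate`, `well`, `strain`, `FSC`, `SSC`, `FL1` (linear scale).
#'
#' @param path CSV file path.
#' @return tibble of events.
#' @export
read_flow_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate", "well", "strain", "FSC", "SSC", "FL1")
  if (!all(need %in% names(df))) {
    stop("flow CSV must have columns: ", paste(need, collapse = ", "))
  }
  as_tibble(df[need])
}

#' @rdname read_flow_events
#' @param events flow event table.
#' @export
write_flow_events <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a generic TSV table
#'
#' List columns (e.g. per-cell object volumes) are collapsed to
#' comma-separated strings.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.list(x[[j]])) {
      x[[j]] <- vapply(x[[j]], function(v) paste(signif(unlist(v), 6),
                                                 collapse = ","), character(1))
    }
  }
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a multi-study catalog as TSV
#'
#' Layout: `gene`, one logical column per study, and a `validated_novel`
#' flag column.
#'
#' @param path TSV path.
#' @return a [study_catalog()].
#' @export
read_catalog_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot("gene" %in% names(df), "validated_novel" %in% names(df))
  studies <- setdiff(names(df), c("gene", "validated_novel"))
  m <- as.matrix(df[studies])
  mode(m) <- "logical"
  rownames(m) <- df$gene
  study_catalog(m, df$gene[as.logical(df$validated_novel)])
}

#' @rdname read_catalog_tsv
#' @param catalog a [study_catalog()].
#' @export
write_catalog_tsv <- function(catalog, path) {
  df <- data.frame(gene = catalog$genes, catalog$membership,
                   validated_novel = catalog$genes %in% catalog$validated_novel,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
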