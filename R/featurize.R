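#' Read a SMILES file
#'
#' One molecule per line: the SMILES string optionally followed by
#' whitespace and an id.  Missing ids are filled as `mol<line>`.
#'
#' @param path path to a `.smi` file.
#' @return Data frame with columns `id` and `smiles`.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no molecules in ", path)
  parts <- strsplit(lines, "[ \t]+")
  smiles <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][[2L]] else paste0("mol", i)
  }, character(1))
  data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Featurize molecules from SMILES
#'
#' Computes one of three descriptor families per molecule:
#' \describe{
#'   \item{`ecfp6`}{circular fingerprint of radius 3 folded to 2048 binary
#'     bits — each bit records whether some atom environment up to three
#'     bonds out is present.}
#'   \item{`maccs`}{the 166 MACCS structural keys (the conventional
#'     unused key-0 padding bit is dropped, so the vector length is
#'     exactly 166).}
#'   \item{`physchem`}{a small panel of 2D physicochemical descriptors
#'     (molecular weight, logP, topological polar surface area, H-bond
#'     donor/acceptor counts, molar refractivity, fluorine count);
#'     non-finite values are imputed to 0 with a warning.}
#' }
#' Chemistry is handled by OpenBabel through the ChemmineOB package.
#' Unparseable SMILES are reported per record (a warning naming the id and
#' offending string) and dropped; if no molecule parses, an error is
#' raised.  For richer descriptor panels computed elsewhere (e.g. a
#' macrocycle-oriented 1613-feature table), load the table with
#' [load_feature_csv()] instead.
#'
#' @param smiles character vector of SMILES strings, or the data frame
#'   returned by [read_smiles()].
#' @param descriptor one of `"ecfp6"`, `"maccs"`, `"physchem"`.
#' @param ids optional ids (taken from the data frame if given there).
#' @return Numeric matrix, one row per successfully parsed molecule,
#'   with rownames = ids, an attribute `descriptor`, and an attribute
#'   `failed` (data frame of id/smiles that did not parse, possibly empty).
#' @export
featurize <- function(smiles, descriptor = c("maccs", "ecfp6", "physchem"),
                      ids = NULL) {
  descriptor <- match.arg(descriptor)
  if (is.data.frame(smiles)) {
    ids <- smiles$id
    smiles <- smiles$smiles
  }
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  if (anyDuplicated(ids)) stop("molecule ids must be unique")
  if (length(smiles) == 0L) stop("no molecules to featurize")
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("featurize() needs the ChemmineOB package")

  one <- function(smi) {
    mol <- ChemmineOB::forEachMol("SMILES", smi, identity)
    switch(descriptor,
      ecfp6 = {
        v <- ChemmineOB::fingerprint_OB(mol, "ECFP6")
        # fold the 4096-bit output to the conventional 2048 bits
        as.numeric(v[1:2048] | v[2049:4096])
      },
      maccs = {
        v <- ChemmineOB::fingerprint_OB(mol, "MACCS")
        as.numeric(v[1:166])  # keys 1..166; padding beyond dropped
      },
      physchem = {
        p <- ChemmineOB::prop_OB(mol)
        as.numeric(p[1, c("MW", "logP", "TPSA", "HBD", "HBA1", "HBA2",
                          "MR", "nF")])
      })
  }

  rows <- vector("list", length(smiles))
  ok <- logical(length(smiles))
  msgs <- character(0)
  for (i in seq_along(smiles)) {
    res <- tryCatch(one(smiles[[i]]), error = function(e) e)
    if (inherits(res, "error")) {
      msgs <- c(msgs, paste0(ids[[i]], ": unparseable SMILES '",
                             smiles[[i]], "'"))
    } else {
      rows[[i]] <- res
      ok[[i]] <- TRUE
    }
  }
  if (!any(ok))
    stop("no molecule could be parsed:\n  ", paste(msgs, collapse = "\n  "))
  if (length(msgs))
    warning("dropped ", length(msgs), " unparseable record(s):\n  ",
            paste(msgs, collapse = "\n  "))

  m <- do.call(rbind, rows[ok])
  rownames(m) <- ids[ok]
  colnames(m) <- switch(descriptor,
    ecfp6 = paste0("ECFP6_", seq_len(ncol(m))),
    maccs = paste0("MACCS_", seq_len(ncol(m))),
    physchem = c("MW", "logP", "TPSA", "HBD", "HBA1", "HBA2", "MR", "nF"))
  if (any(!is.finite(m))) {
    warning("non-finite descriptor values imputed to 0")
    m[!is.finite(m)] <- 0
  }
  attr(m, "descriptor") <- descriptor
  attr(m, "failed") <- data.frame(
    id = ids[!ok], smiles = smiles[!ok], stringsAsFactors = FALSE)
  m
}

#' Read and write feature tables
#'
#' CSV feature tables have an id column, an optional label column and
#' numeric feature columns — the interchange format for descriptor panels
#' computed outside the package (e.g. a 1613-feature macrocycle table).
#'
#' @param path CSV file path.
#' @param id_col name of the id column (default `"id"`).
#' @param label_col name of the 0/1 label column, or `NULL` if the table
#'   is unlabeled.
#' @return `load_feature_csv()`: list with `x` (numeric matrix, rownames =
#'   ids), `labels` (integer vector or `NULL`) and `descriptor_name` (the
#'   file stem).  `write_feature_csv()`: the path, invisibly.
#' @export
load_feature_csv <- function(path, id_col = "id", label_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_col %in% names(df)) stop("no '", id_col, "' column in ", path)
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  labels <- NULL
  drop <- id_col
  if (!is.null(label_col)) {
    if (!label_col %in% names(df))
      stop("no '", label_col, "' column in ", path)
    labels <- coerce_labels(df[[label_col]])
    drop <- c(drop, label_col)
  }
  feat <- df[, setdiff(names(df), drop), drop = FALSE]
  for (nm in names(feat)) {
    v <- feat[[nm]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop("non-numeric value in column '", nm, "'",
           if (!is.na(bad)) paste0(", row ", bad) else "")
    }
  }
  x <- as.matrix(feat)
  rownames(x) <- ids
  list(x = x, labels = labels,
       descriptor_name = tools::file_path_sans_ext(basename(path)))
}

#' @rdname load_feature_csv
#' @param x numeric feature matrix with rownames as ids.
#' @param labels optional 0/1 labels written as a `label` column.
#' @export
write_feature_csv <- function(x, path, labels = NULL) {
  df <- data.frame(id = rownames(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(labels)) df$label <- as.integer(labels)
  df <- cbind(df, as.data.frame(x, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Min-max feature scaling
#'
#' `minmax_fit()` records per-column minima and maxima of the training
#' matrix; `minmax_apply()` maps columns affinely onto \[0, 1\] with those
#' parameters, clipping values outside the training range and mapping
#' constant training columns to 0.  The FNT's Gaussian neurons expect
#' inputs on this scale.
#'
#' @param x numeric training matrix.
#' @return `minmax_fit()`: list with `min` and `max` vectors;
#'   `minmax_apply()`: the scaled matrix.
#' @export
minmax_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("cannot fit scaling on an empty matrix")
  list(min = apply(x, 2L, min), max = apply(x, 2L, max))
}

#' @rdname minmax_fit
#' @param scaling parameters from `minmax_fit()`.
#' @export
minmax_apply <- function(x, scaling) {
  x <- as.matrix(x)
  rng <- scaling$max - scaling$min
  out <- sweep(x, 2L, scaling$min, `-`)
  keep <- rng > 0
  out[, keep] <- sweep(out[, keep, drop = FALSE], 2L, rng[keep], `/`)
  out[, !keep] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}
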