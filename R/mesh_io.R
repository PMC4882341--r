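# ---------------------------------------------------------------------------
# TetGen .node / .ele text round-trip and legacy-VTK field export
# ---------------------------------------------------------------------------

#' Write a tetrahedral mesh as TetGen .node/.ele text files
#'
#' `path` is the stem: `<path>.node` gets `index x y z` lines (1-based,
#' metres) and `<path>.ele` gets `index n1 n2 n3 n4 label` lines. Tissue
#' labels are written as the integer shell codes; the code -> name mapping is
#' written as a comment line in the .ele header.
#'
#' @param mesh a `tet_mesh`.
#' @param path file stem (without extension).
#' @return the stem, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  nodef <- paste0(path, ".node")
  elef <- paste0(path, ".ele")
  n <- nrow(mesh$nodes)
  con <- file(nodef, "w")
  writeLines(sprintf("%d 3 0 0", n), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(n),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  close(con)
  con <- file(elef, "w")
  writeLines(sprintf("%d 4 1", nrow(mesh$tets)), con)
  writeLines(paste0("# labels: ",
                    paste(sprintf("%d=%s", seq_along(mesh$tissue_labels),
                                  mesh$tissue_labels), collapse = " ")), con)
  writeLines(sprintf("%d %d %d %d %d %d", seq_len(nrow(mesh$tets)),
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4], mesh$tissue), con)
  close(con)
  invisible(path)
}

# vectorised fixed-width-table parser with per-line error reporting
parse_table_lines <- function(lines, nfield, file, linenos) {
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  bad <- which(len < nfield)
  if (length(bad)) {
    stop(sprintf("%s line %d: expected %d fields, found %d",
                 file, linenos[bad[1]], nfield, len[bad[1]]))
  }
  x <- suppressWarnings(vapply(toks, function(t) as.numeric(t[seq_len(nfield)]),
                               numeric(nfield)))
  nas <- which(colSums(is.na(x)) > 0)
  if (length(nas)) stop(sprintf("%s line %d: malformed number", file, linenos[nas[1]]))
  t(x)
}

parse_numeric_line <- function(line, nfield, file, lineno) {
  toks <- strsplit(trimws(line), "[ \t]+")[[1]]
  if (length(toks) < nfield) {
    stop(sprintf("%s line %d: expected %d fields, found %d",
                 file, lineno, nfield, length(toks)))
  }
  x <- suppressWarnings(as.numeric(toks[seq_len(nfield)]))
  if (anyNA(x)) stop(sprintf("%s line %d: malformed number", file, lineno))
  x
}

#' Read a TetGen .node/.ele mesh
#'
#' @param path file stem: `<path>.node` and `<path>.ele` must exist.
#' @param tissue_labels optional code -> name mapping; recovered from the
#'   `# labels:` comment when present.
#' @return a `tet_mesh`.
#' @export
read_mesh <- function(path, tissue_labels = NULL) {
  nodef <- paste0(path, ".node")
  elef <- paste0(path, ".ele")
  nl <- readLines(nodef)
  keep <- !grepl("^\\s*(#|$)", nl)
  lineno <- which(keep)
  nl <- nl[keep]
  hdr <- parse_numeric_line(nl[1], 2, nodef, lineno[1])
  nn <- as.integer(hdr[1])
  if (length(nl) - 1 < nn) stop(sprintf("%s: header announces %d nodes, file has %d", nodef, nn, length(nl) - 1))
  body <- parse_table_lines(nl[1 + seq_len(nn)], 4, nodef, lineno[1 + seq_len(nn)])
  nodes <- body[, 2:4, drop = FALSE]

  el <- readLines(elef)
  lab_line <- grep("^# labels:", el, value = TRUE)
  if (is.null(tissue_labels) && length(lab_line)) {
    toks <- strsplit(sub("^# labels:\\s*", "", lab_line[1]), "\\s+")[[1]]
    tissue_labels <- sub("^[0-9]+=", "", toks)
  }
  keep <- !grepl("^\\s*(#|$)", el)
  lineno <- which(keep)
  el <- el[keep]
  hdr <- parse_numeric_line(el[1], 2, elef, lineno[1])
  nt <- as.integer(hdr[1])
  if (length(el) - 1 < nt) stop(sprintf("%s: header announces %d elements, file has %d", elef, nt, length(el) - 1))
  eln <- lineno[1 + seq_len(nt)]
  body <- parse_table_lines(el[1 + seq_len(nt)], 6, elef, eln)
  tets <- matrix(as.integer(body[, 2:5]), nt, 4)
  oob <- which(tets < 1L | tets > nn, arr.ind = TRUE)
  if (nrow(oob)) {
    stop(sprintf("%s line %d: node index out of range [1, %d]",
                 elef, eln[min(oob[, 1])], nn))
  }
  tissue <- as.integer(body[, 6])
  if (is.null(tissue_labels)) tissue_labels <- paste0("tissue", sort(unique(tissue)))
  build_tet_mesh(nodes, tets, tissue = tissue, tissue_labels = tissue_labels)
}

#' Export per-element fields on a mesh to legacy VTK ASCII
#'
#' Writes an unstructured-grid file with the tetrahedra, the tissue code as
#' cell scalars, and any number of named per-cell arrays: length-T numeric
#' vectors become SCALARS, T x 3 matrices become VECTORS.
#'
#' @param mesh a `tet_mesh`.
#' @param fields named list of per-element arrays (may be empty).
#' @param path output file path.
#' @export
write_fields_vtk <- function(mesh, fields = list(), path) {
  n <- nrow(mesh$nodes); Tn <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tet mesh with per-element fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", Tn, 5 * Tn), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", Tn), con)
  writeLines(as.character(rep(10L, Tn)), con)
  writeLines(sprintf("CELL_DATA %d", Tn), con)
  writeLines(c("SCALARS tissue int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$tissue), con)
  for (nm in names(fields)) {
    x <- fields[[nm]]
    if (is.matrix(x) && ncol(x) == 3) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(sprintf("%.9g %.9g %.9g", x[, 1], x[, 2], x[, 3]), con)
    } else {
      writeLines(sprintf("SCALARS %s double 1", nm), con)
      writeLines("LOOKUP_TABLE default", con)
      writeLines(sprintf("%.9g", as.numeric(x)), con)
    }
  }
  invisible(path)
}
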