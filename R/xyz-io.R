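#' @include system-model.R
NULL

## Extended-XYZ dialect: comment line holds space-separated key=value pairs,
## values quoted when they contain spaces; Lattice="ax ay az bx by bz cx cy cz";
## Properties=species:S:1:pos:R:3[:name:T:ncol ...] declares the per-atom
## column layout.

.quoteXYZValue <- function(x) {
  x <- as.character(x)
  if (grepl("[[:space:]]", x)) paste0('"', x, '"') else x
}

.formatInfo <- function(info) {
  paste(vapply(names(info), function(k) {
    v <- info[[k]]
    if (is.numeric(v)) v <- paste(sprintf("%.17g", v), collapse = " ")
    paste0(k, "=", .quoteXYZValue(v))
  }, character(1)), collapse = " ")
}

## Write one extended-XYZ frame to an open connection.
## extra: data.frame of additional per-atom columns (character or integer).
.writeExtXYZFrame <- function(con, elements, coords, info = list(),
                              extra = NULL, coordFmt = "%.17g") {
  n <- length(elements)
  props <- "species:S:1:pos:R:3"
  if (!is.null(extra) && ncol(extra) > 0) {
    for (nm in names(extra)) {
      typ <- if (is.integer(extra[[nm]])) "I" else if (is.numeric(extra[[nm]])) "R" else "S"
      props <- paste0(props, ":", nm, ":", typ, ":1")
    }
  }
  info <- c(info, list(Properties = props))
  writeLines(as.character(n), con)
  writeLines(.formatInfo(info), con)
  body <- character(n)
  for (i in seq_len(n)) {
    line <- paste(elements[i],
                  sprintf(coordFmt, coords[i, 1]),
                  sprintf(coordFmt, coords[i, 2]),
                  sprintf(coordFmt, coords[i, 3]))
    if (!is.null(extra) && ncol(extra) > 0) {
      vals <- vapply(names(extra), function(nm) {
        v <- extra[[nm]][i]
        if (is.double(v)) sprintf(coordFmt, v) else as.character(v)
      }, character(1))
      line <- paste(line, paste(vals, collapse = " "))
    }
    body[i] <- line
  }
  writeLines(body, con)
}

.parseInfoLine <- function(line) {
  out <- list()
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|\\S+)', line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  starts <- m; lens <- attr(m, "match.length")
  for (k in seq_along(starts)) {
    tok <- substr(line, starts[k], starts[k] + lens[k] - 1)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    if (startsWith(val, '"')) val <- substr(val, 2, nchar(val) - 1)
    out[[key]] <- val
  }
  out
}

.parseProperties <- function(spec) {
  toks <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(toks) %% 3 != 0) stop("malformed Properties spec: ", spec)
  data.frame(name = toks[seq(1, length(toks), 3)],
             type = toks[seq(2, length(toks), 3)],
             ncol = as.integer(toks[seq(3, length(toks), 3)]),
             stringsAsFactors = FALSE)
}

#' Read a (multi-frame) extended-XYZ file
#'
#' @param path File path.
#' @return List of frames; each frame is a list with `elements`, `coords`
#'   (n x 3 matrix, Angstrom), `info` (named list of comment-line key-value
#'   strings), and `extra` (data.frame of any additional per-atom columns).
#' @export
readExtXYZ <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L; frameIdx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frameIdx <- frameIdx + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || i + 1L + n > length(lines))
      stop(sprintf("malformed extended-XYZ frame %d at line %d", frameIdx, i))
    info <- .parseInfoLine(lines[i + 1L])
    props <- .parseProperties(info[["Properties"]] %||% "species:S:1:pos:R:3")
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    ncolExpect <- sum(props$ncol)
    if (any(vapply(toks, length, integer(1)) != ncolExpect))
      stop(sprintf("malformed atom line in extended-XYZ frame %d", frameIdx))
    tab <- do.call(rbind, toks)
    col <- 1L; elements <- NULL; coords <- NULL
    extra <- list()
    for (r in seq_len(nrow(props))) {
      cols <- col:(col + props$ncol[r] - 1L)
      vals <- tab[, cols, drop = FALSE]
      if (props$name[r] == "species") {
        elements <- as.character(vals[, 1])
      } else if (props$name[r] == "pos") {
        coords <- matrix(as.numeric(vals), ncol = 3)
      } else {
        v <- as.character(vals[, 1])
        extra[[props$name[r]]] <- switch(props$type[r],
                                         I = as.integer(v), R = as.numeric(v), v)
      }
      col <- col + props$ncol[r]
    }
    info[["Properties"]] <- NULL
    frames[[frameIdx]] <- list(elements = elements, coords = coords,
                               info = info,
                               extra = as.data.frame(extra,
                                                     stringsAsFactors = FALSE))
    i <- i + 2L + n
  }
  frames
}

#' Write a configuration as extended-XYZ
#'
#' One frame with the lattice in the comment line, per-site `site_label` and
#' `mol_id` columns, and the full rigid-body state (template ids, centers of
#' mass, quaternions, conformer indices) stored as comment-line arrays at
#' full double precision, so [readConfigurationXYZ()] round-trips the
#' configuration exactly.
#'
#' @param config A [Configuration].
#' @param path Output path.
#' @param info Extra comment-line key-value pairs.
#' @return `path`, invisibly.
#' @export
writeConfigurationXYZ <- function(config, path, info = list()) {
  st <- siteTable(config)
  L <- config@box@edges
  info <- c(list(
    Lattice = sprintf("%.17g 0 0 0 %.17g 0 0 0 %.17g", L[1], L[2], L[3]),
    mol_template = paste(config@templateId, collapse = " "),
    mol_conformer = paste(config@conformer, collapse = " "),
    mol_com = paste(sprintf("%.17g", t(config@com)), collapse = " "),
    mol_quat = paste(sprintf("%.17g", t(config@quat)), collapse = " ")
  ), info)
  con <- file(path, "w")
  on.exit(close(con))
  .writeExtXYZFrame(con, st$element, st$coords, info = info,
                    extra = data.frame(site_label = st$label,
                                       mol_id = st$mol))
  invisible(path)
}

#' Read a configuration written by [writeConfigurationXYZ()]
#'
#' @param path File path.
#' @param templates Named list of [MoleculeTemplate]s covering every template
#'   id stored in the file.
#' @return A [Configuration].
#' @export
readConfigurationXYZ <- function(path, templates) {
  fr <- readExtXYZ(path)[[1]]
  lat <- as.numeric(strsplit(trimws(fr$info$Lattice), "[[:space:]]+")[[1]])
  if (length(lat) != 9) stop("missing or malformed Lattice entry")
  edges <- lat[c(1, 5, 9)]
  tid <- strsplit(trimws(fr$info$mol_template), "[[:space:]]+")[[1]]
  conf <- as.integer(strsplit(trimws(fr$info$mol_conformer), "[[:space:]]+")[[1]])
  com <- matrix(as.numeric(strsplit(trimws(fr$info$mol_com), "[[:space:]]+")[[1]]),
                ncol = 3, byrow = TRUE)
  quat <- matrix(as.numeric(strsplit(trimws(fr$info$mol_quat), "[[:space:]]+")[[1]]),
                 ncol = 4, byrow = TRUE)
  configuration(box3(edges), templates, tid, com, quat, conf)
}

#' Write a fragment as plain XYZ (engine exchange format)
#'
#' @param fragment A fragment from [makeFragment()].
#' @param path Output path.
#' @param comment Comment-line text.
#' @return `path`, invisibly.
#' @export
writeFragmentXYZ <- function(fragment, path, comment = "fragment") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(fragment$elements)), con)
  writeLines(comment, con)
  writeLines(sprintf("%s %.10f %.10f %.10f", fragment$elements,
                     fragment$coords[, 1], fragment$coords[, 2],
                     fragment$coords[, 3]), con)
  invisible(path)
}
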