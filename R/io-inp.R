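# Abaqus .inp subset interchange: *NODE, *ELEMENT TYPE=C3D4, *NSET, *ELSET.
# The reader is deliberately permissive (keyword casing, blanks, comment
# lines); unknown keyword blocks are skipped with a logged warning and
# unsupported element types are rejected by name.

#' Write a mesh to an Abaqus .inp subset file
#'
#' Emits `*NODE`, one `*ELEMENT, TYPE=C3D4, ELSET=<region>` block per
#' element set, and one `*NSET` block per node set. Coordinates are printed
#' with enough digits for a lossless round trip at 1e-6 mm.
#'
#' @param mesh a `fem_mesh`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("*HEADING", "mandfix mesh export"), con)
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.17g, %.17g, %.17g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  # one element block in global order; regions as *ELSET blocks
  writeLines("*ELEMENT, TYPE=C3D4", con)
  writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$tets)),
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  write_set <- function(kind, name, ids) {
    writeLines(sprintf("*%s, %s=%s", kind, kind, name), con)
    for (i0 in seq(1, length(ids), by = 16))
      writeLines(paste(ids[seq(i0, min(i0 + 15, length(ids)))],
                       collapse = ", "), con)
  }
  for (rg in names(mesh$element_sets))
    write_set("ELSET", rg, mesh$element_sets[[rg]])
  for (sn in names(mesh$node_sets))
    write_set("NSET", sn, mesh$node_sets[[sn]])
  invisible(path)
}

inp_params <- function(line) {
  parts <- strsplit(line, ",")[[1]]
  kv <- list(keyword = toupper(trimws(sub("^\\*", "", parts[1]))))
  for (p in parts[-1]) {
    eq <- strsplit(p, "=")[[1]]
    if (length(eq) == 2)
      kv[[toupper(trimws(eq[1]))]] <- trimws(eq[2])
    else kv[[toupper(trimws(eq[1]))]] <- TRUE
  }
  kv
}

#' Read an Abaqus .inp subset file
#'
#' Supports `*NODE`, `*ELEMENT` with `TYPE=C3D4`, `*NSET` and `*ELSET`
#' (including `GENERATE`). Node and element ids need not be contiguous;
#' they are remapped to 1..n. Unknown keyword blocks are skipped with a
#' warning naming the keyword; non-tetrahedral element types are rejected.
#'
#' @param path input file.
#' @return a `fem_mesh`.
#' @export
read_inp <- function(path) {
  if (!is.character(path) || !nzchar(path) || !file.exists(path))
    stop("read_inp: file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  nid <- integer(0)
  xyz <- list()
  eid <- integer(0)
  conn <- list()
  elset_of <- list()
  nsets <- list()
  elsets <- list()
  mode <- "none"
  cur <- NULL
  skipped <- character(0)
  i <- 0L
  for (raw in lines) {
    i <- i + 1L
    line <- trimws(raw)
    if (!nzchar(line) || startsWith(line, "**")) next
    if (startsWith(line, "*")) {
      kv <- inp_params(line)
      kw <- kv$keyword
      if (kw == "NODE") {
        mode <- "node"
      } else if (kw == "ELEMENT") {
        type <- toupper(kv[["TYPE"]] %||% "")
        if (type != "C3D4")
          stop("read_inp: unsupported element type '", type,
               "' at line ", i, " (only C3D4 is supported)")
        mode <- "element"
        cur <- kv[["ELSET"]]      # NULL: elements belong to no named set
        if (!is.null(cur) && is.null(elsets[[cur]]))
          elsets[[cur]] <- integer(0)
      } else if (kw == "NSET") {
        mode <- if (isTRUE(kv[["GENERATE"]])) "nset_gen" else "nset"
        cur <- kv[["NSET"]] %||% stop("read_inp: *NSET without NSET= at line ", i)
        if (is.null(nsets[[cur]])) nsets[[cur]] <- integer(0)
      } else if (kw == "ELSET") {
        mode <- if (isTRUE(kv[["GENERATE"]])) "elset_gen" else "elset"
        cur <- kv[["ELSET"]] %||% stop("read_inp: *ELSET without ELSET= at line ", i)
        if (is.null(elsets[[cur]])) elsets[[cur]] <- integer(0)
      } else if (kw %in% c("HEADING")) {
        mode <- "skip"
      } else {
        skipped <- c(skipped, kw)
        mode <- "skip"
      }
      next
    }
    vals <- strsplit(line, ",")[[1]]
    if (mode == "node") {
      v <- suppressWarnings(as.numeric(trimws(vals)))
      if (length(v) < 4 || any(is.na(v[1:4])))
        stop("read_inp: malformed node line ", i, ": '", raw, "'")
      nid <- c(nid, as.integer(v[1]))
      xyz[[length(xyz) + 1L]] <- v[2:4]
    } else if (mode == "element") {
      v <- suppressWarnings(as.integer(trimws(vals)))
      if (length(v) < 5 || any(is.na(v[1:5])))
        stop("read_inp: malformed element line ", i, ": '", raw, "'")
      eid <- c(eid, v[1])
      conn[[length(conn) + 1L]] <- v[2:5]
      if (!is.null(cur)) elsets[[cur]] <- c(elsets[[cur]], v[1])
    } else if (mode %in% c("nset", "elset")) {
      v <- suppressWarnings(as.integer(trimws(vals[nzchar(trimws(vals))])))
      if (any(is.na(v)))
        stop("read_inp: malformed set line ", i, ": '", raw, "'")
      if (mode == "nset") nsets[[cur]] <- c(nsets[[cur]], v)
      else elsets[[cur]] <- c(elsets[[cur]], v)
    } else if (mode %in% c("nset_gen", "elset_gen")) {
      v <- suppressWarnings(as.integer(trimws(vals)))
      if (length(v) < 2 || any(is.na(v[1:2])))
        stop("read_inp: malformed GENERATE line ", i, ": '", raw, "'")
      step <- if (length(v) >= 3 && !is.na(v[3])) v[3] else 1L
      ids <- seq.int(v[1], v[2], by = step)
      if (mode == "nset_gen") nsets[[cur]] <- c(nsets[[cur]], ids)
      else elsets[[cur]] <- c(elsets[[cur]], ids)
    }
  }
  if (length(skipped))
    warning("read_inp: skipped unsupported keyword block(s): ",
            paste(unique(skipped), collapse = ", "))
  if (!length(nid)) stop("read_inp: no *NODE block found")
  if (!length(eid)) stop("read_inp: no *ELEMENT block found")
  nodes <- do.call(rbind, xyz)
  nmap <- integer(max(nid))
  nmap[nid] <- seq_along(nid)
  tets <- matrix(nmap[do.call(rbind, conn)], ncol = 4)
  emap <- integer(max(eid))
  emap[eid] <- seq_along(eid)
  element_sets <- lapply(elsets, function(ids) sort(emap[unique(ids)]))
  element_sets <- element_sets[vapply(element_sets, length, 1L) > 0]
  node_sets <- lapply(nsets, function(ids) sort(nmap[unique(ids)]))
  if (!length(element_sets)) {
    element_sets <- list(all = seq_along(eid))
  } else {
    # tolerate overlapping element sets from foreign files: keep the first
    # region claiming each element, in file order
    seen <- logical(length(eid))
    for (rg in names(element_sets)) {
      keep <- !seen[element_sets[[rg]]]
      seen[element_sets[[rg]][keep]] <- TRUE
      element_sets[[rg]] <- element_sets[[rg]][keep]
    }
    element_sets <- element_sets[vapply(element_sets, length, 1L) > 0]
    orphan <- which(!seen)
    if (length(orphan)) element_sets$unassigned <- orphan
  }
  fem_mesh(nodes, tets, node_sets = node_sets, element_sets = element_sets,
           info = list(source = path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
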