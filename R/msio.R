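#' Read a delimited peak table
#'
#' Reads a two-column (m/z, intensity) delimited text file as exported by
#' common MALDI vendor software. The delimiter (comma, tab or semicolon) is
#' auto-detected, a header row is auto-detected by a non-numeric first row,
#' and columns beyond the first two are ignored. Exact duplicate m/z rows are
#' collapsed keeping the maximum intensity.
#'
#' @param path path to the peak table.
#' @param isolate_id,replicate_id identifiers attached to the returned list.
#' @return A [peaklist] sorted by m/z.
#' @export
read_peaklist_table <- function(path, isolate_id, replicate_id = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no peaks in '", path, "'")

  # delimiter auto-detection: the first candidate splitting the first line
  # into >= 2 fields wins
  delim <- NULL
  for (d in c(",", "\t", ";")) {
    if (length(strsplit(lines[[1L]], d, fixed = TRUE)[[1L]]) >= 2L) {
      delim <- d
      break
    }
  }
  if (is.null(delim))
    stop("cannot detect delimiter in '", path,
         "' (expected comma, tab or semicolon)")

  fields <- strsplit(lines, delim, fixed = TRUE)
  parse_row <- function(f) suppressWarnings(as.numeric(trimws(f[1:2])))

  # a header row has no numeric field at all; a row mixing numeric and
  # non-numeric fields is malformed data, reported below
  first <- parse_row(fields[[1L]])
  has_header <- all(is.na(first))
  start <- if (has_header) 2L else 1L
  if (start > length(fields)) stop("no peaks in '", path, "'")

  n <- length(fields) - start + 1L
  mz <- numeric(n); inten <- numeric(n)
  for (k in seq_len(n)) {
    f <- fields[[start + k - 1L]]
    if (length(f) < 2L)
      stop("parse error at line ", line_no[start + k - 1L],
           " of '", path, "': fewer than 2 fields")
    v <- parse_row(f)
    if (anyNA(v))
      stop("parse error at line ", line_no[start + k - 1L],
           " of '", path, "': malformed numeric field")
    mz[k] <- v[1L]; inten[k] <- v[2L]
  }
  if (!n) stop("no peaks in '", path, "'")

  # collapse exact duplicate mz keeping max intensity
  if (anyDuplicated(mz)) {
    inten <- tapply(inten, mz, max)
    mz <- as.numeric(names(inten))
    inten <- as.numeric(inten)
  }
  peaklist(mz, inten, isolate_id = isolate_id, replicate_id = replicate_id)
}

#' Write a peak list as a delimited table
#'
#' Writes tab-separated `mz` and `intensity` columns with a header row, at
#' full double precision so that a read/write round trip is lossless well
#' beyond 6 significant digits.
#'
#' @param x a [peaklist] or `consensus_peaklist`.
#' @param path output path.
#' @export
write_peaklist_table <- function(x, path) {
  stopifnot(inherits(x, c("peaklist", "consensus_peaklist")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("mz\tintensity", con)
  writeLines(sprintf("%.15g\t%.15g", x$peaks$mz, x$peaks$intensity), con)
  invisible(path)
}

#' Read centroided spectra from an mzML file
#'
#' One [peaklist] is returned per spectrum. Isolate and replicate identifiers
#' are parsed from the spectrum id field using a naming pattern with
#' `{isolate}` and `{replicate}` placeholders (default `"{isolate}_{replicate}"`,
#' matching ids such as `"A_r1"`). Profile-mode spectra are rejected unless
#' `force_centroid = TRUE`, in which case the raw arrays are returned for
#' downstream [pick_peaks()].
#'
#' @param path path to an mzML file with centroided spectra.
#' @param pattern naming pattern mapping spectrum ids to identifiers.
#' @param force_centroid accept profile-flagged spectra as-is.
#' @return A list of [peaklist] objects (empty, with a warning, for an mzML
#'   holding no spectra).
#' @export
read_mzml <- function(path, pattern = "{isolate}_{replicate}",
                      force_centroid = FALSE) {
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("invalid mzML file '", path, "': ",
                                          conditionMessage(e)))
  on.exit(mzR::close(ms))
  hd <- suppressWarnings(mzR::header(ms))
  n <- nrow(hd)
  if (n == 0L) {
    warning("mzML file '", path, "' contains no spectra")
    return(list())
  }
  if (!force_centroid && any(!hd$centroided %in% TRUE))
    stop("profile spectra not supported (use force_centroid = TRUE to ",
         "pass them to pick_peaks)")

  ids <- parse_spectrum_ids(hd$spectrumId, pattern)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- mzR::peaks(ms, i)
    mz <- p[, 1L]; inten <- p[, 2L]
    if (anyDuplicated(mz)) {
      inten <- as.numeric(tapply(inten, mz, max))
      mz <- sort(unique(mz))
    }
    out[[i]] <- peaklist(mz, inten, isolate_id = ids$isolate[i],
                         replicate_id = ids$replicate[i])
  }
  out
}

# Turn "{isolate}_{replicate}" into an anchored regex and pull both fields
# out of each spectrum id. All placeholders but the last match lazily so a
# literal separator binds to the last occurrence possible.
parse_spectrum_ids <- function(ids, pattern) {
  parts <- strsplit(pattern, "\\{(isolate|replicate)\\}")[[1L]]
  holes <- regmatches(pattern,
                      gregexpr("\\{(isolate|replicate)\\}", pattern))[[1L]]
  if (!setequal(holes, c("{isolate}", "{replicate}")) || length(holes) != 2L)
    stop("naming pattern must contain {isolate} and {replicate} exactly once")
  esc <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)
  rx <- "^"
  for (i in seq_along(holes)) {
    rx <- paste0(rx, if (i <= length(parts)) esc(parts[i]) else "",
                 if (i < length(holes)) "(.+?)" else "(.+)")
  }
  if (length(parts) > length(holes))
    rx <- paste0(rx, esc(parts[length(parts)]))
  rx <- paste0(rx, "$")
  m <- regmatches(ids, regexec(rx, ids))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("spectrum ids not matching pattern '", pattern, "': ",
         paste(ids[bad], collapse = ", "))
  iso_first <- holes[1L] == "{isolate}"
  list(isolate = vapply(m, `[`, "", if (iso_first) 2L else 3L),
       replicate = vapply(m, `[`, "", if (iso_first) 3L else 2L))
}

#' Write a dendrogram as a Newick tree
#'
#' Serializes an `hclust` dendrogram (see [build_dendrogram()]) with branch
#' lengths equal to merge-height differences (leaves sit at height 0), so the
#' tree is ultrametric with tip depths equal to the root merge height. A
#' single isolate id (character scalar) is accepted as the degenerate one-leaf
#' tree `"A;"`.
#'
#' @param dendrogram an `hclust` object with `labels`, or a single label.
#' @param path output path; `NULL` returns the Newick string invisibly
#'   without writing.
#' @return The Newick string, invisibly.
#' @export
write_newick <- function(dendrogram, path = NULL) {
  if (is.character(dendrogram) && length(dendrogram) == 1L) {
    str <- paste0(dendrogram, ";")
  } else {
    hc <- dendrogram
    stopifnot(inherits(hc, "hclust"))
    labs <- hc$labels
    if (is.null(labs)) labs <- as.character(seq_len(nrow(hc$merge) + 1L))
    if (any(grepl("[(),:;\\s]", labs)))
      stop("isolate labels contain Newick metacharacters")
    node_str <- function(node, parent_height) {
      if (node < 0) {
        sprintf("%s:%.10g", labs[-node], parent_height)
      } else {
        h <- hc$height[node]
        sprintf("(%s,%s):%.10g",
                node_str(hc$merge[node, 1L], h),
                node_str(hc$merge[node, 2L], h),
                parent_height - h)
      }
    }
    root <- nrow(hc$merge)
    h <- hc$height[root]
    str <- sprintf("(%s,%s);",
                   node_str(hc$merge[root, 1L], h),
                   node_str(hc$merge[root, 2L], h))
  }
  if (!is.null(path)) writeLines(str, path)
  invisible(str)
}

#' Write a metabolite association network as GraphML
#'
#' Nodes carry attributes `node_type` (`"isolate"` or `"feature"`),
#' `selected` (`"true"`/`"false"`/`"na"`) and `captured`
#' (`"true"`/`"false"`/`"na"`); the edge set is exactly the MAN's bipartite
#' isolate-feature adjacency. Annotation flags are `"na"` for a MAN that has
#' not been annotated with a selection (see [annotate_man()]).
#'
#' @param man a [build_man()] network.
#' @param path output path.
#' @export
write_graphml <- function(man, path) {
  stopifnot(inherits(man, "man"))
  g <- man_to_igraph(man)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# MAN -> igraph with the attribute scheme used by write_graphml
man_to_igraph <- function(man) {
  iso <- man$isolates
  feat <- if (length(man$features)) paste0("feature_", man$features)
          else character(0)  # paste0 drops zero-length args
  flag <- function(x) {
    if (is.null(x)) return("na")
    ifelse(x, "true", "false")
  }
  sel <- if (is.null(man$selected)) rep("na", length(iso))
         else flag(man$selected[iso])
  cap <- if (is.null(man$captured)) rep("na", length(feat))
         else flag(man$captured[as.character(man$features)])
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(iso), name = iso,
                            node_type = rep("isolate", length(iso)),
                            selected = sel,
                            captured = rep("na", length(iso)))
  g <- igraph::add_vertices(g, length(feat), name = feat,
                            node_type = rep("feature", length(feat)),
                            selected = rep("na", length(feat)),
                            captured = cap)
  if (nrow(man$edges)) {
    ev <- rbind(man$edges$isolate_id,
                paste0("feature_", man$edges$feature_id))
    g <- igraph::add_edges(g, as.vector(ev))
  }
  g
}

#' Write a library selection report as JSON
#'
#' The report lists, per pseudo-phylogenetic group, the group id, the size of
#' the group's distinct small-molecule feature universe, the ordered selected
#' isolates, the running count of captured features and the final captured
#' fraction; and, for the collection, the totals, the threshold and the
#' percent reduction / percent captured summary statistics.
#'
#' @param selection a [prioritize_all()] result.
#' @param path output path.
#' @export
write_selection_report <- function(selection, path) {
  stopifnot(inherits(selection, "library_selection"))
  per_group <- lapply(selection$per_group, function(g)
    list(group_id = g$group_id,
         universe_size = g$universe_size,
         selected = as.list(g$selected),
         cumulative_captured = as.list(g$cumulative_captured),
         captured_fraction = g$captured_fraction,
         captured_features = as.list(g$captured_features)))
  rep <- list(
    per_group = per_group,
    collection = list(
      n_isolates_total = selection$n_isolates_total,
      n_selected_total = selection$n_selected_total,
      n_features_total = selection$n_features_total,
      n_features_captured = selection$n_features_captured,
      threshold = selection$threshold,
      percent_reduction = percent_reduction(selection$n_isolates_total,
                                            selection$n_selected_total),
      percent_captured = if (selection$n_features_total > 0)
        percent_captured(selection$n_features_captured,
                         selection$n_features_total) else NA))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write selected isolate ids, one per line
#'
#' @param selection a [prioritize_all()] result.
#' @param path output path.
#' @export
write_selected_ids <- function(selection, path) {
  stopifnot(inherits(selection, "library_selection"))
  ids <- unlist(lapply(selection$per_group, `[[`, "selected"),
                use.names = FALSE)
  writeLines(as.character(ids), path)
  invisible(path)
}

# Minimal mzML writer (64-bit little-endian, uncompressed). Used to
# materialize simulated collections and test fixtures as standard files;
# not a general-purpose exporter.
write_mzml <- function(peaklists, path, centroided = TRUE) {
  stopifnot(length(peaklists) >= 0L)
  b64 <- function(x)
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                  endian = "little"))
  mode_cv <- if (centroided)
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>'
  arr <- function(accession, name, x) {
    enc <- b64(x)
    sprintf(paste0(
      '<binaryDataArray encodedLength="%d">\n',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '<cvParam cvRef="MS" accession="%s" name="%s" value=""/>\n',
      '<binary>%s</binary>\n</binaryDataArray>'),
      nchar(enc), accession, name, enc)
  }
  specs <- vapply(seq_along(peaklists), function(i) {
    pl <- peaklists[[i]]
    id <- paste0(pl$isolate_id, "_", pl$replicate_id)
    sprintf(paste0(
      '<spectrum index="%d" id="%s" defaultArrayLength="%d">\n%s\n',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
      '<binaryDataArrayList count="2">\n%s\n%s\n</binaryDataArrayList>\n',
      '</spectrum>'),
      i - 1L, id, nrow(pl$peaks), mode_cv,
      arr("MS:1000514", "m/z array", pl$peaks$mz),
      arr("MS:1000515", "intensity array", pl$peaks$intensity))
  }, "")
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" ',
    'URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sw" version="1">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="ic">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="0" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="ic">\n',
    '<spectrumList count="%d" defaultDataProcessingRef="dp">\n%s\n',
    '</spectrumList>\n</run>\n',
    '</mzML>'),
    length(peaklists), paste(specs, collapse = "\n"))
  writeLines(doc, path)
  invisible(path)
}
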