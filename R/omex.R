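#' COMBINE/OMEX archives
#'
#' An OMEX archive is a ZIP container bundling a model entry's files together
#' with a `manifest.xml` describing each file's format and flagging the
#' canonical ("master") file. `omex_archive()` builds one in memory from a
#' manifest table and a payload; [read_omex()] / [write_omex()] convert to and
#' from the ZIP byte representation.
#'
#' @param entries data frame with columns `location` (relative path),
#'   `format` (media-type URI), `master` (logical); one row per payload file.
#' @param payload named list of raw vectors keyed by location.
#' @return An object of class `omex_archive` with elements `entries` and
#'   `payload`.
#' @examples
#' a <- omex_archive(
#'   data.frame(location = "m.xml", format = omex_format_uri("sbml"),
#'              master = TRUE),
#'   list(m.xml = charToRaw("<sbml/>"))
#' )
#' find_master(a)
#' @export
omex_archive <- function(entries, payload) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("location", "format", "master") %in% names(entries)))
  entries$location <- as.character(entries$location)
  entries$format <- as.character(entries$format)
  entries$master <- as.logical(entries$master)
  structure(list(entries = entries, payload = payload),
            class = "omex_archive")
}

MANIFEST_NS <- "http://identifiers.org/combine.specifications/omex-manifest"
MANIFEST_LOCATION <- "manifest.xml"

#' Canonical COMBINE format URIs
#'
#' @param kind one of `"sbml"`, `"sedml"`, `"omex"`, `"manifest"`.
#' @return identifiers.org-style format URI string.
#' @export
omex_format_uri <- function(kind = c("sbml", "sedml", "omex", "manifest")) {
  kind <- match.arg(kind)
  base <- "http://identifiers.org/combine.specifications/"
  switch(kind,
         sbml = paste0(base, "sbml"),
         sedml = paste0(base, "sed-ml"),
         omex = paste0(base, "omex"),
         manifest = paste0(base, "omex-manifest"))
}

# Both identifiers.org and purl.org URI dialects occur in legacy entries.
format_is <- function(format, what) {
  grepl(switch(what,
               sbml = "combine\\.specifications[:/]sbml",
               sedml = "combine\\.specifications[:/]sed-?ml",
               manifest = "omex-manifest",
               omex = "[:/]omex$"),
        format, ignore.case = TRUE)
}

#' @export
print.omex_archive <- function(x, ...) {
  cat("<omex_archive> ", nrow(x$entries), " entries, ",
      length(x$payload), " payload files\n", sep = "")
  for (i in seq_len(nrow(x$entries))) {
    cat(if (isTRUE(x$entries$master[i])) " * " else "   ",
        x$entries$location[i], "  [", x$entries$format[i], "]\n", sep = "")
  }
  invisible(x)
}

#' Read an OMEX archive from ZIP bytes
#'
#' Parses the COMBINE manifest and preserves every payload file byte-exactly.
#' The manifest's optional self-entries (the `"."` root entry and the manifest
#' itself) are tolerated and dropped; [write_omex()] re-emits them.
#'
#' @param archive_bytes raw vector holding a ZIP container.
#' @return An [omex_archive()].
#' @section Errors: `"manifest-absent"` when the ZIP has no `manifest.xml`;
#'   `"corrupt-archive"` when the container cannot be read.
#' @export
read_omex <- function(archive_bytes) {
  files <- zip_extract(archive_bytes)
  if (!(MANIFEST_LOCATION %in% names(files))) {
    vk_stop("manifest-absent", "archive contains no manifest.xml")
  }
  man <- xml2::read_xml(files[[MANIFEST_LOCATION]])
  contents <- xml2::xml_find_all(man, ".//*[local-name()='content']")
  loc <- vapply(contents, function(n) xml2::xml_attr(n, "location"), "")
  fmt <- vapply(contents, function(n) xml2::xml_attr(n, "format"), "")
  mas <- vapply(contents, function(n) {
    isTRUE(tolower(xml2::xml_attr(n, "master")) == "true")
  }, logical(1))
  loc <- sub("^\\./", "", loc)
  keep <- !(loc %in% c(".", "", MANIFEST_LOCATION)) & !format_is(fmt, "manifest")
  payload <- files[setdiff(names(files), MANIFEST_LOCATION)]
  omex_archive(
    data.frame(location = loc[keep], format = fmt[keep], master = mas[keep],
               stringsAsFactors = FALSE),
    payload
  )
}

#' Write an OMEX archive to ZIP bytes
#'
#' Serializes the manifest per the COMBINE manifest schema (including the `"."`
#' root self-entry) and stores every payload file unchanged, so that
#' `read_omex(write_omex(a))` reproduces `a`. Output bytes are deterministic.
#'
#' @param archive an [omex_archive()] satisfying its invariants.
#' @return raw vector (ZIP bytes).
#' @section Errors: `"invalid-archive"` when invariants are violated (e.g. two
#'   master entries, or an entry whose location has no payload).
#' @export
write_omex <- function(archive) {
  stopifnot(inherits(archive, "omex_archive"))
  if (sum(archive$entries$master) != 1) {
    vk_stop("invalid-archive", "archive must have exactly one master entry")
  }
  if (anyDuplicated(archive$entries$location)) {
    vk_stop("invalid-archive", "duplicate manifest locations")
  }
  missing <- setdiff(archive$entries$location, names(archive$payload))
  if (length(missing) > 0) {
    vk_stop("invalid-archive",
            paste("entries without payload:", paste(missing, collapse = ", ")))
  }
  unlisted <- setdiff(names(archive$payload), archive$entries$location)
  if (length(unlisted) > 0) {
    vk_stop("invalid-archive",
            paste("payload without entry:", paste(unlisted, collapse = ", ")))
  }
  man <- xml2::xml_new_root("omexManifest", xmlns = MANIFEST_NS)
  add <- function(location, format, master = NULL) {
    node <- xml2::xml_add_child(man, "content", location = location,
                                format = format)
    if (isTRUE(master)) xml2::xml_set_attr(node, "master", "true")
  }
  add(".", omex_format_uri("omex"))
  add(MANIFEST_LOCATION, omex_format_uri("manifest"))
  for (i in seq_len(nrow(archive$entries))) {
    add(archive$entries$location[i], archive$entries$format[i],
        archive$entries$master[i])
  }
  files <- c(
    stats::setNames(list(charToRaw(as.character(man))), MANIFEST_LOCATION),
    archive$payload[archive$entries$location]
  )
  zip_build(files)
}

#' Structurally validate an OMEX archive
#'
#' Checks the maintenance rules applied during repository curation: zero-size
#' files, filenames with characters outside `[A-Za-z0-9._-]` (or `/` as a path
#' separator), payload files missing from the manifest, manifest entries whose
#' file is missing, and absence of a master entry.
#'
#' @param archive an [omex_archive()].
#' @return data frame of issues with columns `code`, `location`, `detail`;
#'   zero rows iff the archive is clean. Codes are among `empty-file`,
#'   `illegal-filename`, `unlisted-file`, `dangling-entry`, `no-master`.
#' @export
validate_archive <- function(archive) {
  stopifnot(inherits(archive, "omex_archive"))
  iss <- vk_no_issues()
  for (nm in names(archive$payload)) {
    if (length(archive$payload[[nm]]) == 0) {
      iss <- rbind_issues(iss, vk_issues("empty-file", nm, "file of size zero"))
    }
    if (grepl("[^A-Za-z0-9._/-]", nm) || grepl("(^|/)\\.\\.(/|$)", nm)) {
      iss <- rbind_issues(iss, vk_issues("illegal-filename", nm,
                                         "character outside [A-Za-z0-9._-]"))
    }
  }
  unlisted <- setdiff(names(archive$payload), archive$entries$location)
  for (nm in unlisted) {
    iss <- rbind_issues(iss, vk_issues("unlisted-file", nm,
                                       "payload file not in manifest"))
  }
  dangling <- setdiff(archive$entries$location, names(archive$payload))
  for (nm in dangling) {
    iss <- rbind_issues(iss, vk_issues("dangling-entry", nm,
                                       "manifest entry without payload file"))
  }
  if (sum(archive$entries$master) == 0) {
    iss <- rbind_issues(iss, vk_issues("no-master", "",
                                       "no entry flagged as master"))
  }
  iss
}

#' Locate the canonical (master) file of an archive
#'
#' @param archive an [omex_archive()].
#' @return the unique master entry's location string. Any payload type may be
#'   the master; no restriction to SBML.
#' @section Errors: `"no-unique-master"` when zero or several entries are
#'   flagged.
#' @export
find_master <- function(archive) {
  stopifnot(inherits(archive, "omex_archive"))
  m <- which(archive$entries$master)
  if (length(m) != 1) {
    vk_stop("no-unique-master",
            sprintf("%d entries flagged master", length(m)))
  }
  archive$entries$location[m]
}

#' Normalize payload filenames to the curation character set
#'
#' Replaces any character outside `[A-Za-z0-9._-]` (keeping `/` as path
#' separator) with `_`; collisions get numeric suffixes `_2`, `_3`, ... before
#' the extension. Manifest entries and SED-ML-visible names are NOT rewritten
#' here; this is a filename-level maintenance step.
#'
#' @param archive an [omex_archive()].
#' @return list with `archive` (renamed) and `renames` (data frame old/new).
#' @export
normalize_filenames <- function(archive) {
  old <- names(archive$payload)
  new <- gsub("[^A-Za-z0-9._/-]", "_", old)
  # resolve collisions deterministically
  for (i in seq_along(new)) {
    if (sum(new[seq_len(i)] == new[i]) > 1) {
      k <- sum(new[seq_len(i)] == new[i])
      base <- sub("(\\.[^.]*)?$", "", new[i])
      ext <- sub(paste0("^", gsub("([.\\\\])", "\\\\\\1", base)), "", new[i])
      new[i] <- paste0(base, "_", k, ext)
    }
  }
  changed <- old != new
  names(archive$payload) <- new
  idx <- match(archive$entries$location, old)
  archive$entries$location <- ifelse(is.na(idx), archive$entries$location,
                                     new[idx])
  list(archive = archive,
       renames = data.frame(old = old[changed], new = new[changed],
                            stringsAsFactors = FALSE))
}

# Internal helpers used across modules -------------------------------------

# locations of payload files that look like SBML / SED-ML (manifest format
# first, extension + content sniff as fallback)
archive_locations_of <- function(archive, what) {
  locs <- archive$entries$location[format_is(archive$entries$format, what)]
  if (length(locs) == 0) {
    ext <- switch(what, sbml = "\\.(xml|sbml)$", sedml = "\\.sedml$|\\.sed-ml$")
    cand <- names(archive$payload)[grepl(ext, names(archive$payload),
                                         ignore.case = TRUE)]
    sniff <- switch(what, sbml = "<sbml", sedml = "<sedML")
    locs <- cand[vapply(cand, function(l) {
      grepl(sniff, rawToChar(archive$payload[[l]]), fixed = TRUE)
    }, logical(1))]
  }
  locs
}
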