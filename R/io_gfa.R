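# GFA 1.0 assembly graphs.
#
# An assembly_graph is a light S3 container:
#   $segments: data.frame(id, length, depth, sequence or NA)
#   $links:    data.frame(from, from_orient, to, to_orient, overlap)
# Depth is taken from the rd:i: tag (hifiasm-meta), falling back to dp:f:
# and then to 0, so graphs from other producers still load.

new_assembly_graph <- function(segments, links) {
  stopifnot(is.data.frame(segments), is.data.frame(links))
  structure(list(segments = segments, links = links),
            class = "assembly_graph")
}

#' Construct an assembly graph from segment and link tables
#'
#' @param segments data.frame with columns `id`, `sequence` (NA allowed when
#'   `length` is given), optional `length` and `depth`.
#' @param links data.frame with columns `from`, `from_orient`, `to`,
#'   `to_orient` and optional `overlap` (CIGAR, default `"0M"`).
#' @return An `assembly_graph` object.
#' @export
assembly_graph <- function(segments, links = NULL) {
  if (is.null(links)) {
    links <- data.frame(from = character(), from_orient = character(),
                        to = character(), to_orient = character(),
                        overlap = character())
  }
  if (!"length" %in% names(segments)) segments$length <- NA_integer_
  if (!"depth" %in% names(segments)) segments$depth <- 0
  if (!"sequence" %in% names(segments)) segments$sequence <- NA_character_
  no_len <- is.na(segments$length)
  segments$length[no_len] <- nchar(segments$sequence[no_len])
  if (!"overlap" %in% names(links)) links$overlap <- "0M"
  g <- new_assembly_graph(
    segments[, c("id", "length", "depth", "sequence")],
    links[, c("from", "from_orient", "to", "to_orient", "overlap")]
  )
  validate_assembly_graph(g)
}

validate_assembly_graph <- function(g) {
  seg <- g$segments
  if (anyDuplicated(seg$id)) {
    stop("duplicate segment id: ", seg$id[duplicated(seg$id)][1])
  }
  if (any(is.na(seg$length))) stop("segments need a sequence or a length")
  if (any(seg$depth < 0)) stop("segment depth must be >= 0")
  has_seq <- !is.na(seg$sequence)
  if (any(nchar(seg$sequence[has_seq]) != seg$length[has_seq])) {
    stop("segment length disagrees with its sequence length")
  }
  lk <- g$links
  unknown <- setdiff(c(lk$from, lk$to), seg$id)
  if (length(unknown)) stop("link references unknown segment: ", unknown[1])
  if (!all(c(lk$from_orient, lk$to_orient) %in% c("+", "-"))) {
    stop("link orientation must be '+' or '-'")
  }
  g
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat(sprintf("assembly_graph: %d segments (%.0f bp), %d links\n",
              nrow(x$segments), sum(as.numeric(x$segments$length)),
              nrow(x$links)))
  invisible(x)
}

gfa_tag <- function(fields, tag) {
  hit <- grep(paste0("^", tag), fields, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  sub(paste0("^", tag), "", hit[1])
}

#' Read a GFA 1.0 assembly graph
#'
#' Parses S (segment) and L (link) lines. Segment depth is read from the
#' `rd:i:` integer tag when present, else the `dp:f:` float tag, else 0.
#' Segments may carry a `*` sequence if they have an `LN:i:` length tag.
#' Other line types (H, P, ...) are ignored with a message reporting how
#' many were skipped.
#'
#' @param path Path to a GFA file.
#' @return An `assembly_graph`.
#' @export
read_gfa <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  type <- substr(lines, 1, 1)

  s_lines <- lines[type == "S"]
  seg <- lapply(s_lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed S-line: ", l)
    seqtext <- f[3]
    tags <- f[-(1:3)]
    rd <- gfa_tag(tags, "rd:i:")
    dp <- gfa_tag(tags, "dp:f:")
    depth <- if (!is.na(rd)) as.numeric(rd) else if (!is.na(dp)) as.numeric(dp) else 0
    ln <- gfa_tag(tags, "LN:i:")
    if (seqtext == "*") {
      if (is.na(ln)) stop("segment ", f[2], " has neither sequence nor LN tag")
      data.frame(id = f[2], length = as.integer(ln), depth = depth,
                 sequence = NA_character_)
    } else {
      data.frame(id = f[2], length = nchar(seqtext), depth = depth,
                 sequence = toupper(seqtext))
    }
  })
  segments <- do.call(rbind, seg) %||%
    data.frame(id = character(), length = integer(), depth = numeric(),
               sequence = character())

  l_lines <- lines[type == "L"]
  lk <- lapply(l_lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) stop("malformed L-line: ", l)
    data.frame(from = f[2], from_orient = f[3], to = f[4], to_orient = f[5],
               overlap = if (length(f) >= 6L) f[6] else "0M")
  })
  links <- do.call(rbind, lk) %||%
    data.frame(from = character(), from_orient = character(),
               to = character(), to_orient = character(),
               overlap = character())

  n_other <- sum(!type %in% c("S", "L"))
  if (n_other > 0L) {
    message("read_gfa: ignored ", n_other, " non-S/L line(s)")
  }
  validate_assembly_graph(new_assembly_graph(segments, links))
}

#' Write an assembly graph as GFA 1.0
#'
#' Depth is emitted as a `dp:f:` tag (and `rd:i:` when integral).
#'
#' @param graph An `assembly_graph`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gfa <- function(graph, path) {
  seg <- graph$segments
  s <- vapply(seq_len(nrow(seg)), function(i) {
    seqtext <- if (is.na(seg$sequence[i])) "*" else seg$sequence[i]
    tags <- sprintf("LN:i:%d\tdp:f:%.12g", seg$length[i], seg$depth[i])
    if (seg$depth[i] == round(seg$depth[i])) {
      tags <- paste0(tags, sprintf("\trd:i:%d", as.integer(seg$depth[i])))
    }
    sprintf("S\t%s\t%s\t%s", seg$id[i], seqtext, tags)
  }, character(1))
  lk <- graph$links
  l <- sprintf("L\t%s\t%s\t%s\t%s\t%s",
               lk$from, lk$from_orient, lk$to, lk$to_orient, lk$overlap)
  writeLines(c("H\tVN:Z:1.0", s, l), path)
  invisible(path)
}
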