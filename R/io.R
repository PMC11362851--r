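#' Write a gMSA graph
#'
#' The native dialect is JSON with a `blocks` array (id, length_nt,
#' merged_from, rows of genome/contig/i/j/sigma) and a `sequences` array
#' (name, genome, contig, color, vertices), guide first.  Writing is
#' canonical: blocks sorted by id, fixed key order, two-space indentation, so
#' `write_gmsa(read_gmsa(p), q)` is byte-identical to a canonically written
#' `p`.  `format = "tsv"` writes the flattened one-row-per-interval view of
#' [gmsa_flat()] -- a convenience export, not round-trippable.
#'
#' @param g A `gmsa_graph`.
#' @param path Output file path.
#' @param format `"json"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_gmsa <- function(g, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(gmsa_flat(g), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  ord <- order(g$blocks$id)
  blocks <- lapply(ord, function(k) {
    rows <- g$blocks$rows[[k]]
    list(id = jsonlite::unbox(g$blocks$id[k]),
         length_nt = jsonlite::unbox(g$blocks$length_nt[k]),
         merged_from = as.list(g$blocks$merged_from[[k]]),
         rows = lapply(seq_len(nrow(rows)), function(r) {
           list(genome = jsonlite::unbox(rows$genome[r]),
                contig = jsonlite::unbox(rows$contig[r]),
                i = jsonlite::unbox(rows$i[r]),
                j = jsonlite::unbox(rows$j[r]),
                sigma = jsonlite::unbox(rows$sigma[r]))
         }))
  })
  seqs <- lapply(seq_len(nrow(g$sequences)), function(k) {
    list(name = jsonlite::unbox(g$sequences$name[k]),
         genome = jsonlite::unbox(g$sequences$genome[k]),
         contig = jsonlite::unbox(g$sequences$contig[k]),
         color = jsonlite::unbox(g$sequences$color[k]),
         vertices = as.list(g$sequences$vertices[[k]]))
  })
  json <- jsonlite::toJSON(list(blocks = blocks, sequences = seqs),
                           pretty = 2, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read a gMSA graph from JSON or MAF
#'
#' For the native JSON dialect the file is parsed and validated; any invariant
#' violation aborts with the full violation list.  For MAF (Multiple Alignment
#' Format) input, every `a` paragraph becomes one alignment block and each
#' contig's vertex sequence is obtained by sorting that contig's rows by their
#' forward-strand start coordinate, giving the per-contig total order over the
#' blocks.  MAF's 0-based half-open, strand-relative coordinates are converted
#' to 1-based inclusive forward coordinates; reverse-strand rows keep
#' `sigma = -1`.
#'
#' @param path Input file.
#' @param format `"json"` or `"maf"`; guessed from the file extension when
#'   missing.
#' @param guide For MAF input: `"genome:contig"` naming the guide sequence;
#'   defaults to the contig of the first `s` line.
#' @param trim For MAF input: trim comparative sequences to their guide
#'   anchors via [gmsa_trim_to_guide()] before validation (default `TRUE`).
#' @return A validated `gmsa_graph`.
#' @export
read_gmsa <- function(path, format = NULL, guide = NULL, trim = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  format <- format %||%
    (if (grepl("\\.maf$", path, ignore.case = TRUE)) "maf" else "json")
  format <- match.arg(format, c("json", "maf"))
  if (format == "maf") {
    return(read_gmsa_maf(path, guide = guide, trim = trim))
  }
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) {
                  abort(paste0("malformed JSON in ", path, ": ",
                               conditionMessage(e)))
                })
  if (is.null(x$blocks) || is.null(x$sequences)) {
    abort("malformed gMSA JSON: need top-level `blocks` and `sequences`")
  }
  block_tbl <- tibble(
    id = map_chr(x$blocks, function(b) as.character(b$id)),
    length_nt = map_dbl(x$blocks, function(b) as.numeric(b$length_nt)),
    merged_from = map(x$blocks, function(b) {
      as.character(unlist(b$merged_from %||% b$id))
    }),
    rows = map(x$blocks, function(b) {
      tibble(genome = map_chr(b$rows, function(r) as.character(r$genome)),
             contig = map_chr(b$rows, function(r) as.character(r$contig)),
             i = map_dbl(b$rows, function(r) as.numeric(r$i)),
             j = map_dbl(b$rows, function(r) as.numeric(r$j)),
             sigma = map_dbl(b$rows, function(r) as.numeric(r$sigma)))
    })
  )
  seq_tbl <- tibble(
    name = map_chr(x$sequences, function(s) as.character(s$name)),
    genome = map_chr(x$sequences, function(s) as.character(s$genome)),
    contig = map_chr(x$sequences, function(s) as.character(s$contig)),
    color = map_chr(x$sequences, function(s) as.character(s$color)),
    vertices = map(x$sequences, function(s) as.character(unlist(s$vertices)))
  )
  gmsa_graph(block_tbl, seq_tbl, check = TRUE)
}

# MAF `a`/`s` paragraph reader.  No installed R package parses MAF, so this
# small reader handles the standard line format directly.
read_gmsa_maf <- function(path, guide = NULL, trim = TRUE) {
  lines <- readLines(path)
  rows <- list()
  block_no <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    if (startsWith(line, "a")) {
      block_no <- block_no + 1L
      next
    }
    if (!startsWith(line, "s ")) next
    f <- strsplit(line, "[ \t]+")[[1]]
    if (length(f) < 7L) {
      abort(sprintf("malformed MAF `s` line %d: expected 7 fields, got %d",
                    ln, length(f)))
    }
    if (block_no == 0L) {
      abort(sprintf("malformed MAF: `s` line %d before any `a` line", ln))
    }
    src <- f[2]
    dot <- regexpr(".", src, fixed = TRUE)
    genome <- if (dot > 0) substr(src, 1, dot - 1) else src
    contig <- if (dot > 0) substr(src, dot + 1, nchar(src)) else src
    start <- as.numeric(f[3]); size <- as.numeric(f[4])
    strand <- f[5]; src_size <- as.numeric(f[6])
    if (is.na(start) || is.na(size) || is.na(src_size) ||
        !strand %in% c("+", "-")) {
      abort(sprintf("malformed MAF `s` line %d: bad numeric/strand field", ln))
    }
    # 0-based half-open, strand-relative -> 1-based inclusive forward coords
    if (strand == "+") {
      i <- start + 1; j <- start + size; sigma <- 1
    } else {
      i <- src_size - start - size + 1; j <- src_size - start; sigma <- -1
    }
    rows[[length(rows) + 1L]] <-
      tibble(block = sprintf("b%d", block_no), genome = genome,
             contig = contig, i = i, j = j, sigma = sigma)
  }
  if (length(rows) == 0) abort("no alignment rows found in MAF file")
  rows <- bind_rows(rows)

  ids <- unique(rows$block)
  block_tbl <- tibble(
    id = ids,
    length_nt = map_dbl(ids, function(b) {
      r <- rows[rows$block == b, ]
      max(r$j - r$i + 1)
    }),
    merged_from = map(ids, function(b) b),
    rows = map(ids, function(b) {
      r <- rows[rows$block == b, c("genome", "contig", "i", "j", "sigma")]
      as_tibble(r)
    })
  )

  ctg <- unique(paste(rows$genome, rows$contig, sep = ":"))
  guide <- guide %||% ctg[1]
  if (!guide %in% ctg) {
    abort(paste0("guide `", guide, "` not present in MAF (have: ",
                 paste(ctg, collapse = ", "), ")"))
  }
  ctg <- c(guide, setdiff(ctg, guide))
  seq_tbl <- tibble(
    name = ctg,
    genome = sub(":.*$", "", ctg),
    contig = sub("^[^:]*:", "", ctg),
    color = gmsa_palette(length(ctg)),
    vertices = map(ctg, function(cc) {
      gn <- sub(":.*$", "", cc); cg <- sub("^[^:]*:", "", cc)
      r <- rows[rows$genome == gn & rows$contig == cg, ]
      r$block[order(r$i)]
    })
  )
  g <- gmsa_graph(block_tbl, seq_tbl, check = FALSE)
  if (trim && nrow(seq_tbl) > 1) g <- gmsa_trim_to_guide(g)
  v <- gmsa_validate(g)
  if (nrow(v) > 0) {
    abort(c("MAF-derived graph is invalid:",
            stats::setNames(paste(v$rule, "--", v$detail), rep("x", nrow(v)))))
  }
  g
}
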