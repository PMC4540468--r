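#' Write a network (or learning checkpoint) as plain text
#'
#' Sectioned key/value text with dense row-major numeric blocks at 17
#' significant digits, so a round trip is exact in double precision.
#' Matrices written: `V`, `V0`, `b`, `Wexc`, `Winh`, plus any extra
#' named vectors/matrices (e.g. `bhat`, `bsleep`, `step`).
#'
#' @param network a `sheet_network`.
#' @param path output file.
#' @param extra named list of additional numeric vectors/matrices.
#' @export
write_network <- function(network, path, extra = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sheetsampler network K=%d N=%d family=%s",
                     network$K, network$N, network$family), con)
  blocks <- c(list(V = network$V, V0 = network$V0, b = network$b,
                   Wexc = network$Wexc, Winh = network$Winh), extra)
  for (nm in names(blocks)) {
    x <- blocks[[nm]]
    if (is.matrix(x)) {
      writeLines(sprintf("@%s matrix %d %d", nm, nrow(x), ncol(x)), con)
      for (r in seq_len(nrow(x)))
        writeLines(paste(sprintf("%.17g", x[r, ]), collapse = "\t"), con)
    } else {
      writeLines(sprintf("@%s vector %d", nm, length(x)), con)
      writeLines(paste(sprintf("%.17g", x), collapse = "\t"), con)
    }
  }
  writeLines("@fields list", con)
  for (k in seq_len(network$K))
    writeLines(paste(network$fields[[k]], collapse = "\t"), con)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path input file.
#' @return list with the named blocks plus a reassembled `network`.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  i <- 2  # skip header comment
  blocks <- list()
  fields <- NULL
  K <- as.integer(sub(".*K=(\\d+).*", "\\1", lines[1]))
  family <- sub(".*family=(\\w+).*", "\\1", lines[1])
  while (i <= length(lines)) {
    hdr <- strsplit(sub("^@", "", lines[i]), " ")[[1]]
    nm <- hdr[1]; kind <- hdr[2]
    if (kind == "matrix") {
      nr <- as.integer(hdr[3]); nc <- as.integer(hdr[4])
      m <- matrix(0, nr, nc)
      for (r in seq_len(nr))
        m[r, ] <- as.numeric(strsplit(lines[i + r], "\t")[[1]])
      blocks[[nm]] <- m
      i <- i + nr + 1
    } else if (kind == "vector") {
      n <- as.integer(hdr[3])
      blocks[[nm]] <- if (n > 0)
        as.numeric(strsplit(lines[i + 1], "\t")[[1]]) else numeric(0)
      i <- i + 2
    } else {  # fields list: K rows
      fields <- lapply(seq_len(K), function(k)
        as.integer(strsplit(lines[i + k], "\t")[[1]]))
      i <- i + K + 1
    }
  }
  net <- sheet_network(blocks$V, blocks$V0, blocks$b, blocks$Wexc,
                       blocks$Winh, fields = fields, family = family)
  c(blocks, list(network = net))
}
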