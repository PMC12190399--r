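# internal helpers shared across modules

# distances to the adjacent site on each flank, per chromosome.
# `pos` must be sorted ascending within each chromosome. For circular
# chromosomes the gap wraps around; linear ends get Inf.
neighbor_distances <- function(chrom, pos, chrom_len = NULL, circular = character()) {
  dt <- data.table(chrom = chrom, pos = pos, idx = seq_along(pos))
  dt[, `:=`(dl = as.numeric(pos - shift(pos, 1L, type = "lag")),
            dr = as.numeric(shift(pos, 1L, type = "lead") - pos)),
     by = chrom]
  for (cc in intersect(unique(dt$chrom), circular)) {
    L <- chrom_len[[cc]]
    if (is.null(L)) stop("circular chromosome ", cc, " needs a length")
    sel <- which(dt$chrom == cc)
    if (length(sel) >= 2L) {
      wrap <- dt$pos[sel[1L]] + L - dt$pos[sel[length(sel)]]
      dt$dl[sel[1L]] <- wrap
      dt$dr[sel[length(sel)]] <- wrap
    }
  }
  dt[is.na(dl), dl := Inf]
  dt[is.na(dr), dr := Inf]
  list(left = dt$dl, right = dt$dr)
}

# centered box-filter moving average with symmetric shrink at the edges.
# Operates on a complete integer grid; NA entries (offsets with no data)
# are excluded from each window's mean.
box_smooth <- function(values, window = 21L) {
  stopifnot(window %% 2L == 1L)
  h <- (window - 1L) %/% 2L
  n <- length(values)
  pres <- as.numeric(!is.na(values))
  v0 <- ifelse(is.na(values), 0, values)
  cs_v <- cumsum(v0)
  cs_p <- cumsum(pres)
  i <- seq_len(n)
  d <- pmin(h, i - 1L, n - i)
  lo <- i - d
  hi <- i + d
  base_v <- cs_v[pmax(lo - 1L, 1L)]
  base_p <- cs_p[pmax(lo - 1L, 1L)]
  base_v[lo == 1L] <- 0
  base_p[lo == 1L] <- 0
  num <- cs_v[hi] - base_v
  den <- cs_p[hi] - base_p
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# parse "start-end;start-end" intron strings into a list of 2-col matrices
parse_intervals <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s) || s == ".") {
      return(matrix(numeric(0), ncol = 2L,
                    dimnames = list(NULL, c("start", "end"))))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) stop("malformed interval string: ", s)
    m <- matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE,
                dimnames = list(NULL, c("start", "end")))
    if (any(is.na(m)) || any(m[, 1] >= m[, 2]))
      stop("malformed interval string: ", s)
    m
  })
}

format_intervals <- function(lst) {
  vapply(lst, function(m) {
    if (is.null(m) || nrow(m) == 0L) return("")
    paste(sprintf("%d-%d", as.integer(m[, 1]), as.integer(m[, 2])),
          collapse = ";")
  }, character(1))
}

# subtract a set of intervals from one [start, end) interval; all 0-based
# half-open. Returns a matrix of remaining pieces.
interval_subtract <- function(start, end, cuts) {
  pieces <- matrix(c(start, end), ncol = 2L)
  if (is.null(cuts) || nrow(cuts) == 0L) {
    colnames(pieces) <- c("start", "end")
    return(pieces)
  }
  cuts <- cuts[order(cuts[, 1]), , drop = FALSE]
  out <- NULL
  cur <- start
  for (i in seq_len(nrow(cuts))) {
    cs <- max(cuts[i, 1], start); ce <- min(cuts[i, 2], end)
    if (ce <= cs) next
    if (cs > cur) out <- rbind(out, c(cur, cs))
    cur <- max(cur, ce)
  }
  if (cur < end) out <- rbind(out, c(cur, end))
  if (is.null(out)) out <- matrix(numeric(0), ncol = 2L)
  colnames(out) <- c("start", "end")
  out
}

# write a data.table as a headered TSV with a leading tool-version comment
write_pk_tsv <- function(dt, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# phasekin %s", pk_version()), con)
  close(con); on.exit(NULL)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

read_pk_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  fread(path, sep = "\t", skip = if (startsWith(first, "#")) 1L else 0L,
        header = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
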