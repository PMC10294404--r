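# Internal helpers shared across modules.

# Deterministic fan-out of one user-facing seed into per-component streams.
# Rule: child = (seed * 1009 + offset(component)) mod (2^31 - 1), with a fixed
# offset per component name, so regenerating one fixture never perturbs the
# random stream of another.
.CHILD_OFFSETS <- c(model = 11L, tracks = 23L, genes = 37L, mapping = 41L,
                    scores = 53L, annotations = 67L, regions = 71L,
                    train = 83L, counts = 97L)

childSeed <- function(seed, component) {
  if (!component %in% names(.CHILD_OFFSETS))
    stop("unknown seed component: ", component)
  (as.numeric(seed) * 1009 + .CHILD_OFFSETS[[component]]) %% (2^31 - 1)
}

# Transparent text connection: gzfile() reads both plain and gzip-compressed
# files; writers compress iff the path ends in ".gz".
.readConn <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  gzfile(path, open = "rt")
}

.writeConn <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, open = "wt") else file(path, open = "wt")
}

.readAllLines <- function(path) {
  con <- .readConn(path)
  on.exit(close(con))
  readLines(con)
}

.writeAllLines <- function(lines, path) {
  con <- .writeConn(path)
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Run-length encode a per-bin state vector into 0-based half-open bp
# intervals, clipping the final interval to the chromosome length. NA runs
# (unassigned bins) are dropped.
.stateRuns <- function(states, chromLen, binSize) {
  r <- rle(ifelse(is.na(states), -1L, as.integer(states)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != -1L
  data.frame(start = starts[keep] * binSize,
             end = pmin(ends[keep] * binSize, chromLen),
             state = r$values[keep])
}

# Segmentation -> GRanges of merged per-state intervals (bp coordinates).
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
.segmentationRanges <- function(seg) {
  asm <- assembly(seg)
  parts <- lapply(names(stateSeqs(seg)), function(chrom) {
    runs <- .stateRuns(stateSeqs(seg)[[chrom]], chromSizes(asm)[[chrom]],
                       binSize(asm))
    if (nrow(runs) == 0L) return(NULL)
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(start = runs$start + 1L, end = runs$end),
                           state = runs$state)
  })
  # per-chromosome pieces share no seqlevels by construction; combining
  # them is intentional, so the cross-seqlevel warning is noise here
  suppressWarnings(do.call(c, Filter(Negate(is.null), parts)))
}

.checkAssemblyMatch <- function(a, b) {
  if (!identical(chromSizes(a), chromSizes(b)) || binSize(a) != binSize(b))
    stop("assemblies do not match")
  invisible(TRUE)
}

# Pearson correlation that returns NA (with a warning upstream) rather than
# erroring on zero-variance input.
.safeCor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}
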