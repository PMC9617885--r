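# Flat structured-text serialization for ann_model.
# Doubles are written with "%.17g", which round-trips IEEE-754 doubles
# exactly, so a write/read cycle is bit-exact (required so that a model
# trained once can be reloaded for inference without any re-quantization).

fmt_dbl <- function(x) sprintf("%.17g", x)

fmt_row <- function(x) paste(fmt_dbl(x), collapse = " ")

parse_row <- function(line) as.numeric(strsplit(trimws(line), "\\s+")[[1]])

write_matrix_block <- function(con, tag, m) {
  m <- as.matrix(m)
  writeLines(sprintf("%s %d %d", tag, nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m))) writeLines(fmt_row(m[i, ]), con)
}

read_matrix_block <- function(lines, pos, tag) {
  hdr <- strsplit(lines[pos], "\\s+")[[1]]
  if (hdr[1] != tag) stop("expected block '", tag, "', found '", hdr[1], "'")
  nr <- as.integer(hdr[2]); nc <- as.integer(hdr[3])
  m <- matrix(0, nr, nc)
  for (i in seq_len(nr)) m[i, ] <- parse_row(lines[pos + i])
  list(value = m, pos = pos + nr + 1)
}

#' Write an ANN model to a structured text file
#'
#' Stores architecture, activation parameters, per-layer float weights,
#' integer quantization codes with their per-layer scales, and the realized
#' (possibly mismatch-perturbed) values. The round trip through
#' [read_ann_model()] is bit-exact.
#'
#' @param model an [ann_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ann_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("analogrc_ann_model 1", con)
  writeLines(paste("layer_sizes", paste(model$layer_sizes, collapse = " ")), con)
  writeLines(paste("weight_bits", paste(model$weight_bits, collapse = " ")), con)
  writeLines(paste("act_bits", paste(model$act_bits, collapse = " ")), con)
  writeLines(paste("act_full_scale", fmt_dbl(model$act_full_scale)), con)
  writeLines(paste("unit_cap", fmt_dbl(model$unit_cap)), con)
  writeLines(paste("decision_threshold", fmt_dbl(model$decision_threshold)), con)
  writeLines(paste("seed", model$seed), con)
  writeLines(paste("quantized", as.integer(!is.null(model$qweights))), con)
  for (l in seq_along(model$activations)) {
    a <- model$activations[[l]]
    writeLines(sprintf("activation %d %s %s %s %s", l, a$kind,
                       fmt_dbl(a$gain), fmt_dbl(a$saturation),
                       fmt_dbl(a$offset)), con)
  }
  for (l in seq_along(model$weights)) {
    write_matrix_block(con, sprintf("W%d", l), model$weights[[l]])
    write_matrix_block(con, sprintf("b%d", l), matrix(model$biases[[l]], nrow = 1))
    if (!is.null(model$qweights)) {
      qw <- model$qweights[[l]]
      writeLines(paste(sprintf("scale%d", l), fmt_dbl(attr(qw, "step"))), con)
      write_matrix_block(con, sprintf("QW%d", l), attr(qw, "codes"))
      write_matrix_block(con, sprintf("VW%d", l), qw)
      qb <- model$qbiases[[l]]
      writeLines(paste(sprintf("bscale%d", l), fmt_dbl(attr(qb, "step"))), con)
      write_matrix_block(con, sprintf("Qb%d", l), matrix(attr(qb, "codes"), nrow = 1))
      write_matrix_block(con, sprintf("Vb%d", l), matrix(as.numeric(qb), nrow = 1))
    }
  }
  invisible(path)
}

#' Read an ANN model written by [write_ann_model()]
#'
#' @param path file path.
#' @return an [ann_model()], bit-identical to the one written.
#' @export
read_ann_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "analogrc_ann_model")) {
    stop("not an analogrc ANN model file: ", path)
  }
  field <- function(name) {
    line <- lines[startsWith(lines, paste0(name, " "))][1]
    strsplit(line, "\\s+")[[1]][-1]
  }
  layer_sizes <- as.integer(field("layer_sizes"))
  weight_bits <- as.integer(field("weight_bits"))
  act_bits <- as.integer(field("act_bits"))
  n_layers <- length(layer_sizes) - 1
  activations <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    a <- strsplit(lines[startsWith(lines, sprintf("activation %d ", l))][1],
                  "\\s+")[[1]]
    activations[[l]] <- activation_model(a[3], gain = as.numeric(a[4]),
                                         saturation = as.numeric(a[5]),
                                         offset = as.numeric(a[6]))
  }
  model <- ann_model(layer_sizes = layer_sizes, weight_bits = weight_bits,
                     act_bits = act_bits, activations = activations,
                     act_full_scale = as.numeric(field("act_full_scale")),
                     unit_cap = as.numeric(field("unit_cap")),
                     decision_threshold = as.numeric(field("decision_threshold")),
                     seed = as.integer(field("seed")))
  quantized <- as.integer(field("quantized")) == 1L
  pos <- which(startsWith(lines, "W1 "))[1]
  qweights <- qbiases <- if (quantized) vector("list", n_layers) else NULL
  for (l in seq_len(n_layers)) {
    blk <- read_matrix_block(lines, pos, sprintf("W%d", l))
    model$weights[[l]] <- blk$value; pos <- blk$pos
    blk <- read_matrix_block(lines, pos, sprintf("b%d", l))
    model$biases[[l]] <- as.numeric(blk$value); pos <- blk$pos
    if (quantized) {
      scale <- as.numeric(strsplit(lines[pos], "\\s+")[[1]][2]); pos <- pos + 1
      blk <- read_matrix_block(lines, pos, sprintf("QW%d", l)); pos <- blk$pos
      codes <- blk$value
      blk <- read_matrix_block(lines, pos, sprintf("VW%d", l)); pos <- blk$pos
      qw <- blk$value
      attr(qw, "codes") <- codes; attr(qw, "step") <- scale
      qweights[[l]] <- qw
      bscale <- as.numeric(strsplit(lines[pos], "\\s+")[[1]][2]); pos <- pos + 1
      blk <- read_matrix_block(lines, pos, sprintf("Qb%d", l)); pos <- blk$pos
      bcodes <- as.numeric(blk$value)
      blk <- read_matrix_block(lines, pos, sprintf("Vb%d", l)); pos <- blk$pos
      qb <- as.numeric(blk$value)
      attr(qb, "codes") <- bcodes; attr(qb, "step") <- bscale
      qbiases[[l]] <- qb
    }
  }
  model$qweights <- qweights
  model$qbiases <- qbiases
  model
}
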