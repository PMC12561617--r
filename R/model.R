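#' Backbone configuration
#'
#' Describes the convolutional backbone: a short stack (normally four
#' stages) of `conv -> ReLU -> 2x2 max-pool`, with filter counts that grow
#' and kernel sizes that shrink with depth.
#'
#' @param filters Positive integers, output channels per stage
#'   (default `c(64, 128, 256, 512)`; the reduced-feature-map variant uses
#'   `c(8, 16, 32, 64)`).
#' @param kernel_sizes Positive integers, one per stage, non-increasing
#'   (default `c(7, 5, 3, 3)`).
#' @param input_size Side length of the (square) input image in pixels;
#'   must be divisible by `2^length(filters)` so the pooling chain is exact.
#' @param in_channels Input channels (1 for grayscale MRI slices).
#' @return A `backbone_config` object.
#' @export
backbone_config <- function(filters = c(64, 128, 256, 512),
                            kernel_sizes = c(7, 5, 3, 3),
                            input_size = 256, in_channels = 1) {
  stopifnot(length(filters) == length(kernel_sizes),
            length(filters) >= 1, all(filters >= 1), all(kernel_sizes >= 1))
  if (is.unsorted(rev(kernel_sizes)))
    stop("kernel_sizes must be non-increasing with depth")
  structure(list(filters = as.integer(filters),
                 kernel_sizes = as.integer(kernel_sizes),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels)),
            class = "backbone_config")
}

#' Attention block configuration
#'
#' One attention block holds three sub-units; sub-unit `j` pairs a GCT
#' channel gate with spread `gct_cs[j]` and an l2-SAB with kernel size
#' `sab_kernels[j]`.
#'
#' @param sab_kernels Three positive integers `(k1, k2, k3)`.
#' @param gct_cs Three positive reals `(c1, c2, c3)`; default `c(4, 2, 1)`.
#' @return An `attention_block_config` object.
#' @export
attention_block_config <- function(sab_kernels, gct_cs = c(4, 2, 1)) {
  stopifnot(length(sab_kernels) == 3, length(gct_cs) == 3,
            all(sab_kernels >= 1), all(gct_cs > 0))
  structure(list(sab_kernels = as.integer(sab_kernels),
                 gct_cs = as.numeric(gct_cs)),
            class = "attention_block_config")
}

#' Full model specification
#'
#' Declarative description of a network: backbone, an ordered stack of
#' 0-4 attention blocks (block `i` attaches after backbone stage `i`),
#' whether each sub-unit includes the GCT channel gate before its l2-SAB,
#' and the classification head (`flatten -> dense(head_hidden) -> ReLU ->
#' dense(num_classes)` producing raw class scores).
#'
#' @param backbone A [backbone_config()].
#' @param attention_blocks List of [attention_block_config()] objects
#'   (length 0 to the number of backbone stages).
#' @param use_gct Logical; include the GCT gate in every sub-unit.
#' @param head_hidden Hidden width of the first dense layer (default 128).
#' @param num_classes Number of output classes (3 or 4).
#' @return A `model_spec` object.
#' @export
model_spec <- function(backbone = backbone_config(),
                       attention_blocks = list(), use_gct = TRUE,
                       head_hidden = 128, num_classes = 3) {
  stopifnot(inherits(backbone, "backbone_config"), head_hidden >= 1)
  if (!num_classes %in% c(3L, 4L))
    stop("num_classes must be 3 or 4")
  if (length(attention_blocks) > length(backbone$filters))
    stop("more attention blocks than backbone stages")
  for (b in attention_blocks) stopifnot(inherits(b, "attention_block_config"))
  structure(list(backbone = backbone, attention_blocks = attention_blocks,
                 use_gct = isTRUE(use_gct),
                 head_hidden = as.integer(head_hidden),
                 num_classes = as.integer(num_classes)),
            class = "model_spec")
}

#' Reference attention-stack specification
#'
#' The four-block attention stack used in all experiments: blocks 1-2 use
#' l2-SAB kernels (8, 6, 4), block 3 uses (6, 4, 2), block 4 uses
#' (1, 1, 1), and every block pairs them with GCT spreads (4, 2, 1).
#'
#' @param num_classes 3 or 4.
#' @param backbone Backbone to attach the stack to; defaults to the full
#'   64-128-256-512 backbone at 256 x 256.
#' @return A `model_spec` with four attention blocks.
#' @export
reference_attention_spec <- function(num_classes, backbone = backbone_config()) {
  if (!num_classes %in% c(3L, 4L))
    stop("num_classes must be 3 or 4")
  blocks <- list(
    attention_block_config(c(8, 6, 4)),
    attention_block_config(c(8, 6, 4)),
    attention_block_config(c(6, 4, 2)),
    attention_block_config(c(1, 1, 1)))
  model_spec(backbone = backbone, attention_blocks = blocks,
             use_gct = TRUE, num_classes = num_classes)
}

#' Reduced specification for fast CPU experiments
#'
#' The reference attention stack on the reduced-feature-map backbone
#' (filters 8-16-32-64) at a configurable input size. This is the
#' configuration used throughout the package's own tests and examples.
#'
#' @param num_classes 3 or 4.
#' @param input_size Input side length (default 64).
#' @return A `model_spec`.
#' @export
reduced_spec <- function(num_classes = 3, input_size = 64) {
  reference_attention_spec(num_classes,
    backbone_config(filters = c(8, 16, 32, 64), input_size = input_size))
}

#' Build a network from a specification
#'
#' Materializes a `model_spec` into a runnable network: each backbone stage
#' is `conv -> ReLU -> maxpool(2)`, followed by that stage's attention
#' block when present (each of its three sub-units applies GCT then l2-SAB
#' when `use_gct`, else l2-SAB alone), then `flatten -> dense -> ReLU ->
#' dense`. Weights use He initialization; all biases start at zero.
#'
#' @param spec A [model_spec()].
#' @param seed Optional integer; when given, weight initialization is
#'   deterministic.
#' @return An `ansa_net` object.
#' @export
build_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  bb <- spec$backbone
  n_stages <- length(bb$filters)
  if (bb$input_size %% 2^n_stages != 0)
    stop("input_size must be divisible by ", 2^n_stages)
  if (!is.null(seed)) set.seed(seed)

  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  in_ch <- bb$in_channels
  for (i in seq_len(n_stages)) {
    k <- bb$kernel_sizes[i]
    cl <- layer_conv(sprintf("conv%d", i), in_ch, bb$filters[i], k, stage = i)
    # variance-preserving gain: each l2-SAB sub-unit halves activations at
    # initialization (sigma(0) = 1/2 gate), so compensate the stage's conv
    # scale by 2 per sub-unit to keep unit signal variance at init
    if (i <= length(spec$attention_blocks)) cl$W <- cl$W * 2^3
    add(cl)
    add(layer_relu(sprintf("relu%d", i), stage = i))
    add(layer_maxpool(sprintf("pool%d", i), stage = i))
    if (i <= length(spec$attention_blocks)) {
      blk <- spec$attention_blocks[[i]]
      for (j in 1:3) {
        if (spec$use_gct)
          add(layer_gct(sprintf("gct%d_%d", i, j), blk$gct_cs[j], stage = i))
        add(layer_l2sab(sprintf("sab%d_%d", i, j), blk$sab_kernels[j],
                        stage = i))
      }
    }
    in_ch <- bb$filters[i]
  }
  feat <- (bb$input_size / 2^n_stages)^2 * bb$filters[n_stages]
  add(layer_flatten("flatten"))
  add(layer_dense("fc1", feat, spec$head_hidden))
  add(layer_relu("relu_fc1"))
  add(layer_dense("fc2", spec$head_hidden, spec$num_classes))
  structure(list(spec = spec, layers = layers), class = "ansa_net")
}

# index of the layer producing the output of backbone stage `i`
# (after the stage's attention block when present)
stage_output_index <- function(net, i) {
  idx <- which(vapply(net$layers, function(l) l$stage, 0L) == i)
  if (length(idx) == 0) stop("no such backbone stage: ", i)
  max(idx)
}

stage_names <- function(net) {
  s <- vapply(net$layers, function(l) l$stage, 0L)
  sprintf("conv%d", sort(unique(s[s > 0])))
}

#' Count network parameters
#'
#' @param net An `ansa_net`.
#' @param trainable_only Count only parameters that training would update
#'   (excludes frozen base weights, includes LoRA factors).
#' @return A non-negative integer scalar.
#' @export
count_parameters <- function(net, trainable_only = FALSE) {
  total <- 0
  for (l in net$layers) {
    if (!l$type %in% c("conv", "dense", "l2sab")) next
    if (!trainable_only || !isTRUE(l$frozen))
      total <- total + length(l$W) + length(l$b)
    if (!is.null(l$lora))
      total <- total + length(l$lora$A) + length(l$lora$B)
  }
  as.integer(total)
}

#' Ablation grid of a four-block specification
#'
#' Produces the ten model variants of the ablation protocol: attention
#' block count 0 to 4 (keeping blocks `1..n`) crossed with the GCT gate
#' on or off. With zero blocks the two GCT settings describe the identical
#' backbone-only network.
#'
#' @param spec A `model_spec` with four attention blocks.
#' @return A list of ten `model_spec`s, each carrying `n_blocks` and
#'   `use_gct` attributes.
#' @export
ablation_variants <- function(spec) {
  stopifnot(inherits(spec, "model_spec"),
            length(spec$attention_blocks) == 4)
  out <- list()
  for (gct in c(FALSE, TRUE)) {
    for (n in 0:4) {
      v <- model_spec(backbone = spec$backbone,
                      attention_blocks = spec$attention_blocks[seq_len(n)],
                      use_gct = gct, head_hidden = spec$head_hidden,
                      num_classes = spec$num_classes)
      attr(v, "n_blocks") <- n
      attr(v, "use_gct") <- gct
      out[[length(out) + 1L]] <- v
    }
  }
  out
}

#' Predict with a network
#'
#' @param object An `ansa_net`.
#' @param newdata A list of `labeled_image`s, or an `H x W x C x N` array.
#' @param type `"class"` for integer class labels, `"prob"` for softmax
#'   probabilities, `"logits"` for raw scores.
#' @param ... Unused.
#' @return Integer vector, or a `num_classes x N` matrix.
#' @export
predict.ansa_net <- function(object, newdata,
                             type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  x <- if (is.array(newdata) && length(dim(newdata)) == 4L) newdata
       else as_image_batch(newdata)$x
  logits <- net_forward(object, x)$out
  if (type == "logits") return(logits)
  e <- exp(sweep(logits, 2, apply(logits, 2, max)))
  p <- sweep(e, 2, colSums(e), "/")
  if (type == "prob") p else apply(p, 2, which.max)
}

#' Summarize a network layer by layer
#'
#' Runs a single probe input through the network and prints one row per
#' layer: name, type, output shape, and parameter count.
#'
#' @param object An `ansa_net`.
#' @param ... Unused.
#' @return Invisibly, a data frame with the table.
#' @export
summary.ansa_net <- function(object, ...) {
  bb <- object$spec$backbone
  x <- array(0, c(bb$input_size, bb$input_size, bb$in_channels, 1L))
  rows <- list()
  for (l in object$layers) {
    x <- layer_forward(l, x)$out
    np <- if (l$type %in% c("conv", "dense", "l2sab"))
      length(l$W) + length(l$b) +
        (if (is.null(l$lora)) 0L else length(l$lora$A) + length(l$lora$B))
    else 0L
    rows[[length(rows) + 1L]] <- data.frame(
      name = l$name, type = l$type,
      output = paste(dim(x) %||% length(x), collapse = "x"),
      params = np, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  print(tab, row.names = FALSE)
  cat("total parameters:", count_parameters(object), "\n")
  invisible(tab)
}

#' @export
print.ansa_net <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "ansa_net: %d-stage backbone (%s), %d attention block(s), GCT %s, %d classes\n",
    length(s$backbone$filters), paste(s$backbone$filters, collapse = "-"),
    length(s$attention_blocks), if (s$use_gct) "on" else "off",
    s$num_classes))
  cat(sprintf("parameters: %d (%d trainable)\n",
              count_parameters(x), count_parameters(x, trainable_only = TRUE)))
  invisible(x)
}

#' Serialize / restore a model specification as YAML
#'
#' @param spec A `model_spec`.
#' @param path File to write / read.
#' @return `spec_to_yaml` returns `path` invisibly; `spec_from_yaml`
#'   returns a `model_spec`.
#' @export
spec_to_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  doc <- list(
    backbone = list(filters = spec$backbone$filters,
                    kernel_sizes = spec$backbone$kernel_sizes,
                    input_size = spec$backbone$input_size,
                    in_channels = spec$backbone$in_channels),
    attention_blocks = lapply(spec$attention_blocks, function(b)
      list(sab_kernels = b$sab_kernels, gct_cs = b$gct_cs)),
    use_gct = spec$use_gct, head_hidden = spec$head_hidden,
    num_classes = spec$num_classes)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname spec_to_yaml
#' @export
spec_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  model_spec(
    backbone = do.call(backbone_config, doc$backbone),
    attention_blocks = lapply(doc$attention_blocks, function(b)
      attention_block_config(b$sab_kernels, b$gct_cs)),
    use_gct = doc$use_gct, head_hidden = doc$head_hidden,
    num_classes = doc$num_classes)
}
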