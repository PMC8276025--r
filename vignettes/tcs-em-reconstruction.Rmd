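---
title: "Snapshot temporal compression of EM time series: model, decoder, and study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snapshot temporal compression of EM time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Direct electron detectors record in-situ TEM movies at thousands of frames
per second; storing and moving those streams is the bottleneck, not
acquiring them. `tcsem` implements snapshot temporal compressive sensing
for such streams: each group of $B$ consecutive frames
$X_1, \dots, X_B \in \mathbb{R}^{N_x \times N_y}$ is modulated element-wise
by pre-determined binary masks $C_1, \dots, C_B$ and summed on the fly into
a single coded measurement

$$Y \;=\; \sum_{b=1}^{B} X_b \odot C_b ,$$

so the stored payload shrinks by a factor of $B$ once the masks are shared
between encoder and decoder. The encoder is a masked running sum — cheap
enough for on-detector or edge deployment — and all the work moves to the
decoder, a learned network that estimates the $B$ frames back from $Y$.

Reconstruction leans on one physical property of in-situ movies: consecutive
frames are *coherent* (drift and deformation are slow relative to the frame
time). When scene content changes abruptly within a $B$-block the recurrent
decoder has little correlation to exploit, and the method is not the right
tool; that regime is out of scope here.

## The decoder

Normalization first: with per-pixel mask coverage $\sum_k C_k$, the
normalized measurement $\bar Y = Y \oslash \sum_k C_k$ is a crude
time-average of the scene and the entry point of the network, and
$\bar Y \odot C_k$ approximates the $k$-th coded frame. Internally all
intensities are divided by `pixel_peak` so the network operates near the
unit interval; outputs are rescaled at the boundary.

Three stages share one fully convolutional code path, so weights trained on
small clips apply to any frame size:

1. **First-frame CNN** (12 units): the $(B{+}1)$-channel stack
   $[\bar Y, \bar Y \odot C_1, \dots, \bar Y \odot C_B]$ passes through a
   four-layer convolution stage, a three-layer residual block (two
   convolutions + identity skip-add), a windowed self-attention block, and a
   second four-layer stage emitting $\tilde X_1^f$.
2. **Forward recurrent chain**, cells $k = 2..B$: each cell receives the
   previous estimate $\tilde X_{k-1}^f$, a two-channel residual input
   $\bar Y \oplus \big(Y - \sum_{t<k} C_t \odot \tilde X_t^f - \sum_{t>k}
   C_t \odot \bar Y\big)$, and the previous hidden state ($h_1^f = 0$). The
   residual is what remains of the measurement once already-estimated frames
   are explained exactly and future frames are approximated by $\bar Y$;
   with perfect inputs it telescopes to the true coded frame
   $C_k \odot X_k$, and the test suite asserts that identity.
3. **Backward refinement chain**, cells $k = B..1$, structurally identical
   but with its own parameters: residuals use all forward estimates,
   $Y - \sum_{t \ne k} C_t \odot \tilde X_t^f$, the first part is
   $\tilde X_{k+1}^b$ (or $\tilde X_B^f$ at $k = B$), and the hidden chain
   is initialized from $h_B^f$ rather than zero. The backward outputs, in
   ascending order, are the final reconstruction.

Inside a recurrent cell the three input parts pass through three sub-CNNs,
are concatenated and fused, pass through two residual blocks producing the
new hidden unit, and an output sub-CNN emits the frame estimate.

### Choices the architecture text leaves open

* **Fusion width.** Concatenating three `base_channels`-wide sub-CNN outputs
  gives $3c$ channels, but the hidden unit must be $c$-wide; a $3c \to c$
  fusion convolution sits between the concatenation and the residual blocks.
* **Sub-CNN depth.** Each input-part sub-CNN is a single 3×3 convolution and
  the output sub-CNN is two ($c \to c \to 1$); depths are not dictated by the
  decoder's structure and these keep the desk-scale instance CPU-trainable.
* **Widths, kernels, nonlinearity.** Defaults: 3×3 kernels, ReLU, same-size
  padding, `base_channels = 64` (the desk study uses 8, the configured
  minimum). All are `net_config()` surface.
* **Self-attention.** Single-head scaled dot-product attention over spatial
  positions with a learnable output projection and identity skip. On large
  frames attention is computed on non-overlapping windows
  (`attention_window`, default 16 px) to bound the $O((HW)^2)$ score matrix.
* **Residual-input subscripts.** The printed recurrences index the mask
  inside the sums with a fixed $k$; this package reads it as $C_t$ (the
  summation index). With a fixed $C_k$ the residual would not telescope to
  $C_k \odot X_k$ under perfect estimates, which is the stated purpose of
  the term.
* **Backward chain extent.** The backward pass runs through $k = 1$, so
  frame 1 is also refined (rather than terminating the chain at $k = 2$).
* **Initialization.** Seeded He (fan-in) initialization, with two
  stabilizers: the attention output projection starts small (0.1 gain) so
  the identity skip dominates early, and every frame-emitting convolution
  (the CNN's last layer and each cell's output sub-CNN head) starts at 1%
  of He scale. The second matters for deep unrolls: frame estimates re-enter
  later cells through the measurement residuals, and with O(1)-scale initial
  outputs the feedback compounds across a 2B-cell chain; near-zero output
  heads make the initial network quiescent at any B while still receiving
  full gradients.

### Numerical engine

No deep-learning framework ships in the package's dependency set, so the
decoder runs on a small reverse-mode autodiff tape native to the package:
feature maps are `(H·W·N) × C` matrices, convolutions are evaluated as
im2col + BLAS matrix products with the inner loops compiled
(`src/conv.cpp`), ReLU is fused into the convolution kernels, and gradients
flow through the entire unrolled bidirectional recurrence including the
residual-input sums (backpropagation through time). Gradient correctness is
pinned by finite-difference tests against an independent quadruple-loop
convolution reference. Finite-difference checks are run at a generic weight
point: freshly initialized biases are exactly zero, which parks some
pre-activations on the ReLU kink where one-sided numerical derivatives
legitimately disagree with the subgradient convention.

## Training

Supervision pairs a coded measurement with its ground-truth clip, all clips
sharing one mask set (matching deployment, where masks are pre-determined).
By default measurements are encoded from the *noisy* clips while targets are
the *clean* clips, so the decoder learns denoising along with
reconstruction — mirroring the intended behaviour on raw detector frames.
The loss is a weighted sum (default 1, 1) of forward-branch and
backward-branch mean squared error in normalized units; supervising both
branches stabilizes the forward chain that the backward chain feeds on.
Optimization is Adam (lr $10^{-3}$, constant schedule), with per-epoch
validation, early stopping on a 10-epoch validation plateau, and a fully
seeded pipeline: clip synthesis, masks, initialization and batch sampling
all derive from one seed through counter-based streams, so a run is exactly
reproducible and validation clips are disjoint from training clips by
construction.

## The synthetic study

The generator emulates the two scene regimes the method targets:

* **Drifting lattice fringes** (atomic-resolution regime): sums of cosine
  gratings, two fringe families per scene with spacings 3.5–8 px, random
  orientations and phases, background 100–140 on an 8-bit scale, rigid
  drift 0.3–1.2 px/frame (coherence preserved; the generator enforces
  $|v| \le 2$ px/frame as the coherent-movie regime), optionally windowed by
  a shrinking particle envelope.
* **Moving fibers** (large-feature regime): dark Gaussian-profile ribbons
  (widths 3–8 px, depths 60–130) on a bright background, each advancing up
  to 1 column/frame.

Detector noise is Poisson–Gaussian: counts drawn at a dose of 400 expected
electrons per pixel at full scale plus additive readout noise
($\sigma = 2$), then clamped at zero. These values model a reasonably
well-exposed in-situ acquisition; they were fixed when the generator was
written and define the study conditions for every result below. What the
generator does *not* emulate: physical TEM image formation (multislice,
contrast transfer function), beam-induced structural change, or scene cuts
— so passing tests demonstrate the codec's behaviour on coherent,
noise-limited video, not microscope realism.

The desk-scale study (`desk_study()`): B = 4, 32×32 clips, 200 training and
24 validation clips (70% lattice / 30% fiber mix), batch size 2, 2000 Adam
steps, 8-channel decoder — about 9 minutes on one CPU core. Evaluation uses
12 held-out 32×32 clips from the training distribution plus 6 held-out
96×96 lattice-only fixtures, where the decoder is compared against:

* the **naive baseline** — $\bar Y$ replicated $B$ times (training-free
  lower bound);
* the **rate-matched JPEG baseline** — each noisy frame JPEG-compressed to
  at most $1/B$ of its raw byte size (quality found by bisection; if even
  quality 1 exceeds the budget the frame is flagged and scored at
  quality 1), scored against the clean truth like everything else. Masks
  are excluded from byte accounting on both sides, being pre-shared and
  reusable.

The B-sweep comparison (B = 4 vs B = 8) trains both operating points with a
shared shortened budget of 800 steps — identical protocol except B — to
keep the full suite inside a practical CPU budget; the trend (quality
non-increasing in B) is what is asserted, not absolute levels.

### What the desk-scale study shows — and what it cannot

Under these conditions the trained decoder beats the naive baseline by
several dB on held-out clips, and validation loss converges monotonically
at the decile-median level. Two caveats define the limits of desk scale:

* **JPEG at B = 4 is a strong opponent.** A budget of one quarter of the
  raw frame bytes lands standard JPEG near quality 50 on 96×96 frames —
  close to the Poisson noise floor of the fixtures — so at this operating
  point JPEG's mean PSNR against clean truth exceeds the small decoder's.
  The regime where coded-snapshot reconstruction overtakes JPEG is higher
  compression (the budget shrinks as $1/B$ while the measurement stays one
  frame) combined with heavier noise and a full-capacity trained decoder;
  the desk-scale instance documents the machinery honestly rather than that
  headline inequality.
* **Absolute fidelity is capacity-limited.** An 8-channel decoder trained
  for 2000 CPU steps is far from the saturation regime of the full-scale
  architecture; numbers from `desk_study()` are comparative, not
  state-of-the-art claims.

## Degenerate inputs and edge policies

* **Zero mask coverage.** $\bar Y$'s divisor can be zero at pixels no mask
  covers ($\approx 6\%$ of pixels at $B = 4$, density 0.5). Policy:
  $\bar Y = 0$ there, a flag grid records the pixels, and a warning is
  raised; `generate_masks(guarantee_coverage = TRUE)` redraws such pixels
  when i.i.d. masks are not required.
* **Accumulator width.** Measurements are summed in double precision and
  stored at 16-bit (exact for integer-valued frames with
  $B \cdot \mathrm{peak} \le 65535$) or scaled 32-bit float otherwise —
  never clipped to the input bit depth.
* **PSNR sentinel.** Identical frames would give infinite PSNR; the value
  is capped at a documented 100 dB.
* **FFT peak contrast.** The Bragg-retention diagnostic divides the peak
  magnitude near $\pm f$ by the median magnitude in a surrounding annulus;
  an essentially empty annulus (pure spectral line) is floored at
  $10^{-9}$ of the spectrum maximum so the ratio stays finite and
  deterministic.
* **Provenance.** Measurements carry `(B, mask_seed, pixel_peak)`; masks
  carry `(B, shape, seed, density)`. Normalization and decoding refuse
  mismatched pairings — the dominant practical failure mode of mask-coded
  acquisition.

## Known limitations

* The backward chain must wait for the full forward pass; latency is one
  $B$-block by construction.
* Binary masks only (the coded-aperture hardware model); non-binary or
  learned masks are out of scope.
* The JPEG baseline uses the ubiquitous sequential 8-bit codec dialect;
  video codecs (which exploit temporal redundancy themselves) are a
  different comparison and are not implemented.
* Scene-cut detection (choosing when *not* to compress) is future work in
  the underlying method and is not attempted here.
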