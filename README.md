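# braingcn

Discriminative analysis of case–control brain-imaging cohorts with graph
convolutional networks over multimodal brain graphs, in R.

The motivating application is schizophrenia diagnosis from combined
structural and resting-state functional MRI, where reduced regional
gray-matter volume and functional dysconnectivity are the expected disease
signatures; the pipeline itself applies to any two-group connectomics cohort.

Each subject is represented as a brain graph: nodes are atlas regions of
interest (ROIs), node features are six regional structural/functional
measures, and binary edges come from proportionally thresholded connectivity
matrices. A hierarchical GCN with TopK pooling classifies the graphs, and a
node-selection-frequency saliency table ranks the regions the pooling layers
retain. Because clinical MRI cohorts are rarely shareable, the package
includes a seeded synthetic multimodal cohort generator with planted group
effects, so the full pipeline is reproducible and testable end to end with no
imaging data.

## The model

**Node features** (per ROI): mean gray-/white-matter voxel value (GMV, WMV);
amplitude of low-frequency fluctuation (ALFF, mean one-sided FFT amplitude
over 0.01–0.08 Hz, globally normalized per subject); regional homogeneity
(ReHo, Kendall's W over a voxel and its 26-connected neighbours, normalized
likewise); structural/functional degree centrality (sDC/fDC, row sums of the
weighted connectivity matrices). Feature sets: sMRI = (GMV, WMV, sDC),
fMRI = (ReHo, ALFF, fDC), or all six.

**Edges**: the gray matter matrix GMM(i,j) = exp(−symKL(d_i, d_j)) between
kernel density estimates of ROI voxel values; the functional brain matrix
FBM(i,j) = |Pearson r| between ROI mean time series; and GMM-FBM, the sum of
the two after separate min–max normalization. A binary graph keeps exactly
the top fraction *p* of edges (10% for 90-ROI atlases, 5% for 246-ROI,
at/above the Erdős–Rényi floor 2 ln N / N). Three edge kinds × three feature
sets give 9 graph types per atlas, 18 across both reference atlas sizes.

**Classifier**: three blocks of graph convolution
H′ = ReLU(D̃^(−1/2) Ã D̃^(−1/2) H W) → TopK pooling
(y = Hp/‖p‖₂, keep ⌈ratio·N⌉ nodes, gate by tanh y) → readout (columnwise
max ‖ mean); the three readouts are summed and classified by a fully
connected head with batch normalization and dropout. Training: Adam on
cross-entropy, early stopping on an internal validation split. The network,
its hand-derived backward pass and the optimizer are implemented in plain R
(verified against finite differences in the tests).

**Saliency**: each training subject contributes the 20 top-scored survivors
of the last pooling layer; a ROI's score is its selection frequency over
20 · n_train.

## Worked example

The numbered drivers under `analysis/` run the whole study on the synthetic
cohort (120 subjects, 90 ROIs, ten affected ROIs with a −1 SD gray-matter
shift and a 0.7 coupling reduction in patients):

```sh
Rscript analysis/01_simulate_cohort.R      # writes results/cohort/
Rscript analysis/02_features_connectomes.R # features + connectivity matrices
Rscript analysis/03_train_evaluate.R       # 10-repeat split evaluation
Rscript analysis/04_saliency.R             # saliency of the last pooling layer
Rscript analysis/05_demographics.R         # group statistics from summaries
Rscript analysis/06_sparsity_sweep.R       # optional, ~15 min
```

Output actually printed by steps 02–05 on this cohort (seed 1):

```
mean control-minus-patient GMV, affected ROIs: 0.0996     # planted: 0.1
mean control-minus-patient GMV, unaffected ROIs: -0.0002

N90: FBM & sMRI+fMRI         mean accuracy 1.000  AUC 1.000
N90: FBM & sMRI              mean accuracy 0.956  AUC 0.984

affected ROIs in top-10: 0
affected ROIs in bottom-10: 8

  variable            statistic         value   p
  sex (male/female)   Yates chi-squared 6.379   1.155e-02
  education (years)   Welch t           6.264   1.297e-09
```

Reading: the generator's planted gray-matter decrement (0.1) is recovered;
the multimodal graph type separates patients from controls perfectly and
beats the structural-only features, as only the functional coupling plus the
GMV shift jointly identify patients; the demographic statistics recompute
the published reference values (6.378, 6.260) from summary data alone. The
saliency lines show a genuine negative result of the method under planted
*deficits*: the network encodes the group difference by **de-selecting** the
affected, feature-poor ROIs, so they concentrate at the bottom — not the
top — of the selection-frequency ranking. The methods vignette
(`vignettes/multimodal-brain-graph-gcn.Rmd`) analyses this inversion.

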