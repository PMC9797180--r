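cohort,category,feature,regions_failed
GE,GradientOrientHistogram,InterQuartileRange,4
GE,GradientOrientHistogram,Kurtosis,4
GE,GradientOrientHistogram,MeanAbsoluteDeviation,4
GE,GradientOrientHistogram,MedianAbsoluteDeviation,4
GE,GradientOrientHistogram,Percentile,4
GE,GradientOrientHistogram,PercentileArea,4
GE,GradientOrientHistogram,Quantile,4
GE,GradientOrientHistogram,Range,4
GE,GradientOrientHistogram,Skewness,4
GE,GLCM3D,AutoCorrelation,1
GE,GLCM3D,InverseDiffMomentNorm,4
GE,GLCM3D,InverseDiffNorm,4
GE,GLCM3D,SumAverage,3
GE,IntensityHistGaussFit,GaussAmplitude,3
GE,IntensityHistGaussFit,GaussArea,3
GE,IntensityHistGaussFit,GaussMean,3
GE,IntensityHistGaussFit,GaussStd,3
GE,IntensityHistGaussFit,HistArea,3
GE,IntensityHistGaussFit,NumberOfGauss,3
Siemens,GradientOrientHistogram,InterQuartileRange,4
Siemens,GradientOrientHistogram,Kurtosis,4
Siemens,GradientOrientHistogram,MeanAbsoluteDeviation,4
Siemens,GradientOrientHistogram,MedianAbsoluteDeviation,4
Siemens,GradientOrientHistogram,Percentile,4
Siemens,GradientOrientHistogram,PercentileArea,4
Siemens,GradientOrientHistogram,Quantile,4
Siemens,GradientOrientHistogram,Range,4
Siemens,GradientOrientHistogram,Skewness,4
Siemens,GLCM2D,Energy,4
Siemens,GLCM2D,Entropy,3
Siemens,GLCM3D,Energy,4
Siemens,GLCM3D,Entropy,3
Siemens,GLCM3D,InverseDiffMomentNorm,4
Siemens,GLCM3D,InverseDiffNorm,4
Siemens,GLCM3D,MaxProbability,4
Siemens,GrayRunLength2D,GrayLevelNonuniformity,1
Siemens,GrayRunLength2D,HighGrayLevelRunEmpha,1
Siemens,GrayRunLength2D,LongRunEmphasis,1
Siemens,GrayRunLength2D,LongRunHighGrayLevelEmpha,1
Siemens,GrayRunLength2D,LongRunLowGrayLevelEmpha,1
Siemens,GrayRunLength2D,LowGrayLevelRunEmpha,1
Siemens,GrayRunLength2D,RunLengthNonuniformity,1
Siemens,GrayRunLength2D,RunPercentage,1
Siemens,GrayRunLength2D,ShortRunEmphasis,1
Siemens,GrayRunLength2D,ShortRunHighGrayLevelEmpha,1
Siemens,GrayRunLength2D,ShortRunLowGrayLevelEmpha,1
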