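organ,modality,direction,mean_mm
liver,AX_MR,dX,2.6
liver,AX_MR,dY,6.2
liver,AX_MR,dZ,4.9
liver,AX_MR,euclidean,8.3
liver,COR_MR,dX,4.1
liver,COR_MR,dY,5.7
liver,COR_MR,dZ,6.0
liver,COR_MR,euclidean,9.4
liver,CT,dX,2.3
liver,CT,dY,2.2
liver,CT,dZ,8.3
liver,CT,euclidean,9.0
kidney_mean,AX_MR,dX,1.1
kidney_mean,AX_MR,dY,1.6
kidney_mean,AX_MR,dZ,5.6
kidney_mean,AX_MR,euclidean,6.1
kidney_mean,COR_MR,dX,1.2
kidney_mean,COR_MR,dY,1.7
kidney_mean,COR_MR,dZ,6.3
kidney_mean,COR_MR,euclidean,6.8
kidney_mean,CT,dX,1.7
kidney_mean,CT,dY,1.0
kidney_mean,CT,dZ,3.6
kidney_mean,CT,euclidean,4.6
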