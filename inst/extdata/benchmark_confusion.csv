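id,group,feature,clusterer,predicted,healthy,infected,ground
pca_kmeans,model,pca,kmeans,healthy,4972,465,0
pca_kmeans,model,pca,kmeans,infected,0,1378,0
pca_kmeans,model,pca,kmeans,ground,64,595,11213
pca_fcm,model,pca,fcm,healthy,4972,425,0
pca_fcm,model,pca,fcm,infected,0,1417,0
pca_fcm,model,pca,fcm,ground,64,596,11213
pca_dp,model,pca,dp,healthy,4841,0,0
pca_dp,model,pca,dp,infected,6,1852,0
pca_dp,model,pca,dp,ground,189,586,11213
lle_kmeans,model,lle,kmeans,healthy,4703,66,0
lle_kmeans,model,lle,kmeans,infected,113,1878,0
lle_kmeans,model,lle,kmeans,ground,220,494,11213
lle_fcm,model,lle,fcm,healthy,4647,62,0
lle_fcm,model,lle,fcm,infected,149,1891,0
lle_fcm,model,lle,fcm,ground,240,485,11213
lle_dp,model,lle,dp,healthy,4757,2,0
lle_dp,model,lle,dp,infected,111,1984,0
lle_dp,model,lle,dp,ground,168,452,11213
ss_kmeans,model,ss,kmeans,healthy,4852,228,0
ss_kmeans,model,ss,kmeans,infected,14,1682,0
ss_kmeans,model,ss,kmeans,ground,170,528,11213
ss_fcm,model,ss,fcm,healthy,4775,0,0
ss_fcm,model,ss,fcm,infected,14,1718,0
ss_fcm,model,ss,fcm,ground,247,720,11213
ss_dp,model,ss,dp,healthy,4635,0,6
ss_dp,model,ss,dp,infected,153,1944,0
ss_dp,model,ss,dp,ground,248,488,11213
bc_kmeans,model,bc,kmeans,healthy,4829,0,0
bc_kmeans,model,bc,kmeans,infected,0,1764,0
bc_kmeans,model,bc,kmeans,ground,207,674,11213
bc_fcm,model,bc,fcm,healthy,4666,56,0
bc_fcm,model,bc,fcm,infected,142,1896,0
bc_fcm,model,bc,fcm,ground,228,486,11213
bc_dp,model,bc,dp,healthy,4908,106,0
bc_dp,model,bc,dp,infected,0,1843,0
bc_dp,model,bc,dp,ground,128,489,11213
feature_pca,by_feature,pca,,healthy,14785,890,0
feature_pca,by_feature,pca,,infected,6,4647,0
feature_pca,by_feature,pca,,ground,317,1777,33639
feature_lle,by_feature,lle,,healthy,14107,130,0
feature_lle,by_feature,lle,,infected,373,5753,0
feature_lle,by_feature,lle,,ground,628,1431,33639
feature_ss,by_feature,ss,,healthy,14262,228,6
feature_ss,by_feature,ss,,infected,181,5344,0
feature_ss,by_feature,ss,,ground,665,1736,33639
feature_bc,by_feature,bc,,healthy,14403,162,0
feature_bc,by_feature,bc,,infected,142,5503,0
feature_bc,by_feature,bc,,ground,563,1649,33639
clusterer_kmeans,by_clusterer,,kmeans,healthy,19356,759,0
clusterer_kmeans,by_clusterer,,kmeans,infected,127,6702,0
clusterer_kmeans,by_clusterer,,kmeans,ground,661,2291,44852
clusterer_fcm,by_clusterer,,fcm,healthy,19060,543,0
clusterer_fcm,by_clusterer,,fcm,infected,305,6922,0
clusterer_fcm,by_clusterer,,fcm,ground,779,2287,44852
clusterer_dp,by_clusterer,,dp,healthy,19141,108,0
clusterer_dp,by_clusterer,,dp,infected,270,7623,0
clusterer_dp,by_clusterer,,dp,ground,733,2015,44852
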